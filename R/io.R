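# Plain-text projection container: a one-line JSON header carrying type,
# shape, detector spec, energy window and provenance metadata, followed by
# the payload as whitespace-separated numbers in array order (full
# precision, lossless round-trip).

FORMAT_VERSION <- "spectdecon-proj-1"

spec_to_list <- function(spec) unclass(spec)

spec_from_list <- function(lst) {
  detector_spec(raw_grid = unlist(lst$raw_grid),
                raw_pitch = lst$raw_pitch,
                precond_grid = unlist(lst$precond_grid),
                precond_pitch = lst$precond_pitch,
                anode_pitch = lst$anode_pitch,
                n_layers = lst$n_layers,
                layer_thickness = lst$layer_thickness,
                mu_total = lst$mu_total, mu_pe = lst$mu_pe)
}

#' Write a projection to a text container
#'
#' Serializes a `raw_projection` or `precond_projection` losslessly: a
#' one-line JSON header (format version, shape, detector spec, energy
#' window, acquisition metadata) followed by the numeric payload at full
#' precision.
#'
#' @param x the projection object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(x, path) {
  if (inherits(x, "raw_projection")) {
    type <- "raw"; payload <- x$counts
    extra <- list(energy_window = x$energy_window, meta = x$meta)
  } else if (inherits(x, "precond_projection")) {
    type <- "precond"; payload <- x$values
    extra <- list(n_iter = x$n_iter, final_ll = x$final_ll, meta = x$meta)
  } else stop("x must be a raw_projection or precond_projection")
  header <- jsonlite::toJSON(c(list(format = FORMAT_VERSION, type = type,
                                    dim = dim(payload),
                                    spec = spec_to_list(x$spec)),
                               extra),
                             auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  writeLines(paste(sprintf("%.17g", as.numeric(payload)), collapse = " "),
             con)
  invisible(path)
}

#' Read a projection from a text container
#'
#' @param path file written by [write_projection()].
#' @return the reconstructed projection object.
#' @export
read_projection <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) stop("not a projection container: ", path)
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]),
                  error = function(e) stop("corrupt container header: ", path))
  if (is.null(hdr$format) || hdr$format != FORMAT_VERSION)
    stop("unsupported container format in ", path)
  vals <- scan(text = lines[2], quiet = TRUE)
  dm <- unlist(hdr$dim)
  if (length(vals) != prod(dm))
    stop(sprintf("payload length %d does not match declared shape %s",
                 length(vals), paste(dm, collapse = "x")))
  spec <- spec_from_list(hdr$spec)
  if (hdr$type == "raw") {
    counts <- array(vals, dm)
    if (all(counts == round(counts))) storage.mode(counts) <- "integer"
    new_raw_projection(spec, counts,
                       energy_window = unlist(hdr$energy_window),
                       meta = as.list(hdr$meta))
  } else if (hdr$type == "precond") {
    structure(list(values = array(vals, dm), spec = spec,
                   n_iter = hdr$n_iter, ll_trace = NULL,
                   final_ll = unlist(hdr$final_ll),
                   precond_grid = dm[2:3], meta = as.list(hdr$meta)),
              class = "precond_projection")
  } else stop("unknown projection type: ", hdr$type)
}

#' Serialize a blur filter set to YAML
#'
#' @param filters a [blur_filter_set()].
#' @param path output path.
#' @export
write_blur_filters <- function(filters, path) {
  yaml::write_yaml(list(band_halfwidth_mm = filters$band_halfwidth_mm,
                        sigma = apply(filters$sigma, 1, as.numeric,
                                      simplify = FALSE),
                        objective = as.numeric(filters$objective)),
                   path)
  invisible(path)
}

#' @rdname write_blur_filters
#' @export
read_blur_filters <- function(path) {
  y <- yaml::read_yaml(path)
  blur_filter_set(do.call(rbind, y$sigma), y$band_halfwidth_mm,
                  y$objective)
}
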