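# Posterior stream container and tabular I/O.
#
# A posterior stream is the frame-wise output of a phonological analysis
# front end: one row per 10-ms frame, one column per phonological class,
# each entry the posterior probability that the class is active.

#' Construct a posterior stream
#'
#' @param posteriors numeric matrix, frames x 21, values in \[0, 1\].
#' @param attributes character vector of the 21 class names (must include
#'   `"silence"` and be unique). Defaults to [pd_attributes()].
#' @param frame_period frame period in seconds.
#' @param provenance `"synthetic"` or `"external"`.
#' @return A `posterior_stream` object.
#' @export
posterior_stream <- function(posteriors, attributes = pd_attributes(),
                             frame_period = 0.01,
                             provenance = c("synthetic", "external")) {
  provenance <- match.arg(provenance)
  posteriors <- as.matrix(posteriors)
  if (ncol(posteriors) != length(attributes))
    stopf("posterior matrix has %d columns; expected %d",
          ncol(posteriors), length(attributes))
  if (anyDuplicated(attributes)) stopf("attribute names must be unique")
  if (!"silence" %in% attributes) stopf("attribute names must include 'silence'")
  if (length(posteriors) && (min(posteriors) < 0 || max(posteriors) > 1))
    stopf("posterior values must lie in [0, 1]")
  colnames(posteriors) <- attributes
  structure(list(posteriors = posteriors, attributes = attributes,
                 frame_period = frame_period, provenance = provenance),
            class = "posterior_stream")
}

#' @export
print.posterior_stream <- function(x, ...) {
  cat(sprintf("<posterior_stream> %d frames x %d attributes (%.0f ms frame, %s)\n",
              nrow(x$posteriors), ncol(x$posteriors),
              x$frame_period * 1000, x$provenance))
  invisible(x)
}

#' Write a posterior stream to headered CSV (with optional binary sidecar)
#'
#' The CSV has exactly 21 named columns (one per attribute) and one row per
#' frame.  `sidecar = TRUE` additionally writes a compact float32 binary
#' next to the CSV (same path with extension `.bin`).
#'
#' @param stream a `posterior_stream`.
#' @param path output CSV path.
#' @param sidecar also write the binary sidecar?
#' @return `path`, invisibly.
#' @export
write_posteriors <- function(stream, path, sidecar = FALSE) {
  stopifnot(inherits(stream, "posterior_stream"))
  df <- as.data.frame(round(stream$posteriors, 6))
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    bin <- sub("\\.[^.]+$", ".bin", path)
    con <- file(bin, "wb")
    writeBin(dim(stream$posteriors), con, size = 4, endian = "little")
    writeBin(as.numeric(t(stream$posteriors)), con, size = 4, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a posterior stream from CSV
#'
#' Validates the schema strictly: exactly the 21 expected attribute columns
#' and every value in \[0, 1\]; violations report the offending column or
#' row.
#'
#' @param path CSV path.
#' @param attributes expected attribute names.
#' @param provenance provenance tag to attach.
#' @return A `posterior_stream`.
#' @export
read_posteriors <- function(path, attributes = pd_attributes(),
                            provenance = "external") {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(attributes, names(df))
  if (length(missing))
    stopf("posterior file %s is missing attribute column(s): %s",
          path, paste(missing, collapse = ", "))
  extra <- setdiff(names(df), attributes)
  if (length(extra))
    stopf("posterior file %s has unexpected column(s): %s",
          path, paste(extra, collapse = ", "))
  m <- as.matrix(df[, attributes, drop = FALSE])
  bad <- which(m < 0 | m > 1 | is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("posterior value out of [0, 1] at row %d (column %s) in %s",
          bad[1, 1], attributes[bad[1, 2]], path)
  posterior_stream(m, attributes, provenance = provenance)
}
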