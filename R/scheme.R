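#' Multi-shell diffusion acquisition scheme
#'
#' Per-volume b-values (s/mm^2), unit gradient directions, and
#' reverse-phase-encode flags for a diffusion series, in acquisition order.
#'
#' @param bvals Numeric vector of b-values, s/mm^2, one per volume.
#' @param bvecs 3 x n matrix of gradient directions (columns). Directions for
#'   b > 0 volumes must be unit length; b = 0 rows may be zero.
#' @param reverse Logical vector flagging reverse-phase-encode volumes
#'   (acquired only for distortion estimation; excluded from model fits).
#' @return A `diffusion_scheme` object.
#' @export
diffusion_scheme <- function(bvals, bvecs, reverse = rep(FALSE, length(bvals))) {
  bvals <- as.numeric(bvals)
  if (any(bvals < 0)) stop("b-values must be non-negative")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop("'bvecs' must be a 3 x n matrix matching length(bvals)")
  nrm <- sqrt(colSums(bvecs^2))
  bad <- bvals > 0 & abs(nrm - 1) > 1e-4
  if (any(bad)) stop("gradient directions for b > 0 volumes must be unit vectors")
  if (length(reverse) != length(bvals)) stop("'reverse' length mismatch")
  structure(list(bvals = bvals, bvecs = bvecs, reverse = as.logical(reverse)),
            class = "diffusion_scheme")
}

#' @export
print.diffusion_scheme <- function(x, ...) {
  tab <- shell_table(x)
  cat(sprintf("<diffusion_scheme> %d volumes (%d reverse-PE)\n",
              length(x$bvals), sum(x$reverse)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabulate the shell structure of a diffusion scheme
#'
#' @param scheme A [diffusion_scheme()].
#' @param forward_only Count only forward-phase-encode volumes (default),
#'   mirroring the convention that the direction count of a protocol excludes
#'   reverse-phase-encode calibration volumes.
#' @return A data frame with columns `bval` and `n_volumes`, sorted by b.
#' @export
shell_table <- function(scheme, forward_only = TRUE) {
  keep <- if (forward_only) !scheme$reverse else rep(TRUE, length(scheme$bvals))
  b <- scheme$bvals[keep]
  ub <- sort(unique(b))
  data.frame(bval = ub,
             n_volumes = vapply(ub, function(x) sum(b == x), integer(1)))
}

#' Read and write FSL-style bvals/bvecs files
#'
#' `read_bvals_bvecs()` parses the plain-text convention used by FSL and most
#' diffusion tooling: `bvals` holds one whitespace-separated row of b-values,
#' `bvecs` three rows holding the x, y and z direction components.
#'
#' @param bvals_path,bvecs_path File paths.
#' @return A [diffusion_scheme()] (with all `reverse` flags `FALSE`; the flag
#'   is a session-level annotation that the text format does not carry).
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  m <- as.matrix(utils::read.table(bvecs_path))
  if (nrow(m) != 3L) stop("'bvecs' file must have exactly 3 rows")
  dimnames(m) <- NULL
  diffusion_scheme(bvals, m)
}

#' @rdname read_bvals_bvecs
#' @param scheme A [diffusion_scheme()].
#' @export
write_bvals_bvecs <- function(scheme, bvals_path, bvecs_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecs_path)
  invisible(list(bvals = bvals_path, bvecs = bvecs_path))
}
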