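#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor optim pf pt qf qt quantile rnorm runif sd
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_skate <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "skate3d_error")))
}

warn_skate <- function(fmt, ..., class) {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "skate3d_warning")))
}

# row-wise euclidean norm of an n x 3 matrix
row_norm <- function(m) sqrt(rowSums(m * m))

# row-wise cross product of two n x 3 matrices
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# canonical fixed-precision number formatting used by all writers so that
# byte-identical output is guaranteed for identical inputs
fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[!is.finite(x)] <- ""
  out
}

as_matrix3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = FALSE)
  stopifnot(ncol(x) == 3)
  x
}
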