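# internal helpers shared across modules

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# measurement-table column names: s00x, s00y, s00z, ..., s11z
.meas_cols <- function(n_sensors = 12L) {
  paste0(rep(sprintf("s%02d", seq_len(n_sensors) - 1L), each = 3L),
         c("x", "y", "z"))
}

# evaluate `code` under a temporary RNG seed, restoring the caller's RNG state;
# NULL seed uses (and advances) the current RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive per-run child seeds from one master seed (31-bit, reproducible)
.child_seeds <- function(master_seed, n) {
  .with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

#' Extract the per-sensor reading matrix from a measurement row
#'
#' @param measurements A measurement table (wide: `t` plus `s00x` ... columns,
#'   tesla); only the row selected by `row` is used.
#' @param row Row index (default 1).
#' @return A numeric n_sensors x 3 matrix in tesla.
#' @export
measurement_matrix <- function(measurements, row = 1L) {
  cols <- grep("^s[0-9]{2}[xyz]$", names(measurements), value = TRUE)
  if (length(cols) == 0L || length(cols) %% 3L != 0L) {
    stop("measurement table has no complete sNNx/sNNy/sNNz column triplets",
         call. = FALSE)
  }
  cols <- cols[order(cols)]
  matrix(as.numeric(measurements[row, cols]), ncol = 3L, byrow = TRUE,
         dimnames = list(unique(substr(cols, 1L, 3L)), c("x", "y", "z")))
}
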