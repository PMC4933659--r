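# internal helpers shared across modules

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          allow_lower = TRUE, allow_upper = TRUE,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

# area columns of a peptide table, in m = 0..Lmax order
.area_cols <- function(df) {
  cols <- grep("^area_m[0-9]+$", names(df), value = TRUE)
  cols[order(as.integer(sub("^area_m", "", cols)))]
}

# matrix of areas (rows = spectra, cols = m0..mLmax, NA beyond each row's L)
.area_matrix <- function(df) {
  as.matrix(df[, .area_cols(df), drop = FALSE])
}
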