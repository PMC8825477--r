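# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# nearest-match of fragment sizes against a reference set; returns index into
# `ref` or NA when nothing lies within `tol` bp
match_allele <- function(size, ref, tol = 1.0) {
  if (length(ref) == 0L) return(rep(NA_integer_, length(size)))
  vapply(size, function(s) {
    d <- abs(ref - s)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }, integer(1))
}

# weighted mode of integer values; ties broken toward `prefer`, then larger
weighted_mode <- function(x, w = NULL, prefer = NULL) {
  stopifnot(length(x) > 0L)
  w <- w %||% rep(1, length(x))
  tot <- tapply(w, x, sum)
  vals <- as.integer(names(tot))
  best <- vals[tot == max(tot)]
  if (length(best) > 1L && !is.null(prefer) && prefer %in% best) return(prefer)
  max(best)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
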