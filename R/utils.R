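recycle_int <- function(x, n) {
  x <- as.integer(x)
  if (length(x) == n) return(x)
  if (length(x) == 1L) return(rep(x, n))
  stop("length mismatch: cannot recycle vector of length ", length(x),
       " to ", n, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
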