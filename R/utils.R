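# internal helpers

# round to `digits` decimals with ties going away from zero (half-up),
# matching how clinical tables print percentages
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mal <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "malprofiler_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_mal(sprintf("`%s` must be TRUE or FALSE", name), "validation_error")
  x
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop_mal(sprintf("`%s` must be a number in [%s, %s]", name, min, max),
             "validation_error")
  x
}
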