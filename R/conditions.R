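# Classed error conditions so callers can distinguish failure modes with
# tryCatch()/expect_error(class = ...). Each class is "structembed_<what>".

se_stop <- function(class, msg, ..., call. = FALSE) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("structembed_", class), "structembed_error")))
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
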