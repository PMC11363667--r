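# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# run code with a temporary RNG state; NULL seed leaves the current stream alone
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

fmt1 <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f", digits = 1))
fmt2 <- function(x) ifelse(is.na(x), "-", formatC(x, format = "f", digits = 2))

stop_sdb <- function(..., class) {
  stop(structure(
    class = c(class, "sdbscreen_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
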