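# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_pos_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

# evaluate `expr` under a locally seeded RNG, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ">2"-style right-censored IC50 markers used in cohort CSVs
format_ic50 <- function(value, censored) {
  out <- formatC(value, format = "g", digits = 15)
  out[censored] <- paste0(">", formatC(value[censored], format = "g", digits = 15))
  out[is.na(value)] <- NA_character_
  out
}

parse_ic50 <- function(x) {
  x <- as.character(x)
  censored <- !is.na(x) & startsWith(x, ">")
  value <- suppressWarnings(as.numeric(sub("^>", "", x)))
  bad <- !is.na(x) & is.na(value)
  if (any(bad)) {
    stop(sprintf("unparseable IC50 value(s): %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  list(value = value, censored = censored)
}
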