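# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# collapse runs of whitespace, trim ends
squeeze_ws <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

stop_if_not_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single non-NA character string", call. = FALSE)
  invisible(x)
}

# all-character data.table with stable column order; "" treated as missing
as_chr_dt <- function(df) {
  dt <- data.table::as.data.table(df)
  for (j in names(dt)) {
    v <- as.character(dt[[j]])
    v[!is.na(v) & v == ""] <- NA_character_
    data.table::set(dt, j = j, value = v)
  }
  dt
}

# seeded RNG scope that restores the caller's RNG state on exit
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
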