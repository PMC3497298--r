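## small shared helpers; nothing here is exported

`%||%` <- function(a, b) if (is.null(a)) b else a

## round half away from zero (round() in R rounds half to even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## lowercase alphanumeric tokens of a free-text name; hyphens, slashes,
## parentheses all act as separators, so "ATP-ase" -> c("atp", "ase")
name_tokens <- function(x) {
  x <- tolower(as.character(x))
  regmatches(x, gregexpr("[a-z0-9]+", x))
}

is_valid_pdb_id <- function(x) {
  grepl("^[0-9][0-9A-Za-z]{3}$", as.character(x))
}

is_valid_go_id <- function(x) {
  grepl("^GO:[0-9]{7}$", as.character(x))
}

## EC number: four dot-separated fields, first numeric, the rest numeric or
## a "-" wildcard
is_valid_ec <- function(x) {
  grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", as.character(x))
}

## strict ISO-8601 calendar date parsing; returns Date with NA for bad input
parse_iso_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  shaped <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[shaped] <- suppressWarnings(as.Date(x[shaped], format = "%Y-%m-%d"))
  out
}

## strip an optional chain suffix ("1htw_A" -> "1htw"); the accounting unit
## is the 4-character entry ID
strip_chain <- function(x) {
  sub("^([0-9][0-9A-Za-z]{3})_[0-9A-Za-z]+$", "\\1", as.character(x))
}

## run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## stop() with a call-free, stage-prefixed message
fail <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

## split a data.frame into a named list by key, preserving row order and
## first-appearance group order
split_by <- function(df, key) {
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  split(df, factor(df[[key]], levels = unique(df[[key]])))
}

## write a tab-separated table with a header, UTF-8, LF endings
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

read_tsv <- function(path, stage = "io") {
  if (!file.exists(path)) fail(stage, "input file not found: ", path)
  utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
}

check_columns <- function(df, expected, path, stage) {
  if (!identical(names(df), expected)) {
    fail(stage, "unexpected columns in ", path, ": got [",
         paste(names(df), collapse = ", "), "], expected [",
         paste(expected, collapse = ", "), "]")
  }
  invisible(df)
}
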