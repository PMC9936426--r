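# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable 32-bit hash of an R object (provenance stamping)
#'
#' djb2-style string hash over a deparsed representation; used to stamp
#' output files with a configuration fingerprint. Not cryptographic.
#'
#' @param x any R object.
#' @return an 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  # h <- (h * 33 + byte) mod 2^31 ; stays exactly representable in doubles
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# format numbers for TSV artifacts: 6 significant digits by default
fmt_num <- function(x, full_precision = FALSE) {
  if (full_precision) format(x, digits = 17, scientific = FALSE)
  else signif(x, 6)
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# write a TSV with '#'-prefixed metadata header lines
write_tsv_with_meta <- function(df, path, meta = character(),
                                full_precision = FALSE) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (m in meta) writeLines(paste0("# ", m), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num, full_precision = full_precision)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "# ")
  utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

stop_cnet <- function(..., class = "cnet_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
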