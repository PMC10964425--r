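# internal helpers shared across modules

#' @noRd
stopf <- function(fmt, ..., class = "gutweb_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Pipeline stages draw their own random numbers; a single run-level seed is
#' expanded deterministically so each stage is independently reproducible.
#' The result stays below 2^31 - 1.
#'
#' @param seed integer run-level seed.
#' @param stage character stage name.
#' @return integer seed for the stage.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483563)
}

#' @noRd
.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483563L)
  invisible(NULL)
}

# write a data.frame as UTF-8 TSV with "." decimals, no quoting
#' @noRd
.write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @noRd
.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}
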