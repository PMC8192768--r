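#' @import methods
#' @importFrom stats dbinom fisher.test t.test predict runif setNames
#' @importFrom utils head read.delim write.table
NULL

## The 20 standard one-letter amino-acid codes, the unmutated token and the
## token for positions a sequence does not cover (VL-only truncations, or
## positions belonging to other germlines' insertions).
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
X_TOKEN <- "X"
MISSING_TOKEN <- "."

#' Token vocabulary of the somatic-mutation encoding
#'
#' @return Character vector: the 20 amino-acid codes, `"X"` (germline-identical
#'   position) and `"."` (position not covered by the sequence).
#' @export
smutTokens <- function() c(AA_CODES, X_TOKEN, MISSING_TOKEN)

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so generation is a pure function of its inputs.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

.log_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)

## Leveled logging; threshold from options(ALtox.log.level = "INFO"/"DEBUG").
al_log <- function(level, ...) {
  thr <- toupper(getOption("ALtox.log.level", "WARN"))
  if (.log_levels[[level]] >= .log_levels[[thr]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Validate an amino-acid sequence; `what` names the record in errors.
check_aa <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_CODES))
  if (length(bad))
    stop(sprintf("%s contains non-standard residue '%s' at position %d",
                 what, chars[bad[1]], bad[1]), call. = FALSE)
  invisible(TRUE)
}
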