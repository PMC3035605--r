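# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a global seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer((((as.numeric(seed) %% m) * 31 + as.numeric(offset) * 7919) %% m))
}

#' The ordered developmental stage axis
#'
#' Mitotic cycles 10-13 followed by the cellularization sub-stages of cycle
#' 14; every time profile in the package is indexed on this 8-point axis.
#'
#' @return Character vector of the 8 stage labels in temporal order.
#' @export
stage_levels <- function() c("C10", "C11", "C12", "C13", "14A", "14B", "14C", "14D")

check_sample_meta <- function(samples) {
  need <- c("sample_id", "sex", "stage", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop("sample metadata must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(samples$sex %in% c("F", "M"))) {
    stop("sample sex must be 'F' or 'M'", call. = FALSE)
  }
  if (!all(samples$stage %in% stage_levels())) {
    stop("unknown stage label(s): ",
         paste(setdiff(unique(samples$stage), stage_levels()), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(samples$sex, samples$stage, samples$replicate)
  if (anyDuplicated(key)) {
    stop("(sex, stage, replicate) combinations must be unique", call. = FALSE)
  }
  invisible(samples)
}

is_autosome <- function(arm) arm != "X"

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
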