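## Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages draw from seeds derived deterministically from the
#' master seed and a stage label, so that e.g. the discovery and replication
#' outcome draws are independent streams while the whole study remains a pure
#' function of the master seed.
#'
#' @param seed master integer seed.
#' @param ... labels (stage name, which-study, protein index, ...) hashed into
#'   the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
subSeed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

## argument checkers: fail with the offending field named, so configuration
## errors are actionable.
.checkCount <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop("invalid configuration: '", field, "' must be a positive integer",
         call. = FALSE)
  as.integer(x)
}

.checkFraction <- function(x, field, lo = 0, hi = 1,
                           lo.open = FALSE, hi.open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo.open) x > lo else x >= lo) &&
    (if (hi.open) x < hi else x <= hi)
  if (!ok)
    stop("invalid configuration: '", field, "' must lie in ",
         if (lo.open) "(" else "[", lo, ", ", hi,
         if (hi.open) ")" else "]", call. = FALSE)
  as.numeric(x)
}

## squared Pearson correlation between dosage vectors; NA (zero variance)
## treated as 0 so monomorphic variants never block greedy pruning.
.r2 <- function(x, y) {
  r <- suppressWarnings(stats::cor(x, y))
  if (is.na(r)) 0 else r * r
}

## variant matching key: chrom:pos plus the unordered allele pair
.variantKey <- function(chrom, pos, a1, a2) {
  swap <- a1 > a2
  lo <- ifelse(swap, a2, a1)
  hi <- ifelse(swap, a1, a2)
  paste(chrom, pos, lo, hi, sep = ":")
}

.isPalindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[a1]) & comp[a1] == a2
}
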