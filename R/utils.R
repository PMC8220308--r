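## Shared constants and small helpers.

#' The six eukaryotic supergroups used for LECA filtering
#'
#' Families present in at least one member of every one of these supergroups
#' are taken to trace back to the last eukaryotic common ancestor, because
#' eukaryotic inheritance is treated as strictly vertical.
#'
#' @return Character vector of the six supergroup names.
#' @export
#' @examples
#' eukSupergroups()
eukSupergroups <- function() {
  c("Archaeplastida", "Opisthokonta", "SAR", "Hacrobia", "Excavata",
    "Mycetozoa")
}

## Reserved archaeal group label for the asgard superphylum.
ASGARD_GROUP <- "asgard"

DOMAINS <- c("eukaryote", "bacteria", "archaea")

## The 20 standard amino acids; X is additionally accepted on input.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Deterministic polynomial string hash (mod 2^31 - 1), returned as hex.
## Used for content-addressed cluster ids and run manifests; doubles are
## exact here because 31 * (2^31 - 1) < 2^53.
.polyHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 7
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

## Content-addressed id for a set of member keys.
.contentId <- function(members, prefix) {
  paste0(prefix, .polyHash(paste(sort(members), collapse = "|")))
}

## Derive a 31-bit seed for a named substream from a base seed, so that a
## module's draws do not depend on how many draws other modules made.
.deriveSeed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")),
               collapse = "/")
  h <- .polyHash(key)
  as.integer(strtoi(h, 16L) %% 2147483562)
}

## Evaluate expr under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Round half away from zero (presentation-layer rounding for percentages;
## round() would round half to even).
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Nearest-name suggestion for unknown config keys.
.suggestKey <- function(key, known) {
  d <- adist(key, known, ignore.case = TRUE)
  known[which.min(d)]
}
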