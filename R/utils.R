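## Internal helpers: circular coordinate arithmetic and k-mer extraction.

## map arbitrary positions onto [1, L]
modPos <- function(x, L) ((x - 1L) %% L) + 1L

## circular gap (number of bases strictly between position a and position b
## walking forward from a to b); 0 when b == a + 1
circGapFwd <- function(a, b, L) (b - a - 1L) %% L

## all k-mers of a character scalar as a character vector (forward order)
seqKmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

seqChar <- function(x) {
  if (methods::is(x, "PlastomeRecord")) return(as.character(plastomeSeq(x)))
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet"))
    return(as.character(x))
  toupper(as.character(x))
}

## merge seed positions on a shared diagonal into maximal runs.
## i: sorted integer positions; returns data.frame(i1, i2) of run bounds.
seedRuns <- function(i) {
  if (length(i) == 0L) return(data.frame(i1 = integer(), i2 = integer()))
  i <- sort(unique(i))
  brk <- c(TRUE, diff(i) != 1L)
  grp <- cumsum(brk)
  data.frame(i1 = tapply(i, grp, min), i2 = tapply(i, grp, max),
             row.names = NULL)
}

## deterministic RNG scope
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
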