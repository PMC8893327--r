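# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixtureOnce <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

tinyBundle <- function() fixtureOnce("bundle", {
  buildReference(1e5, nChroms = 1L, nTeFamilies = 3L, nIge = 10L,
                 seed = 101)
})

tinyPlan <- function() fixtureOnce("plan", {
  randomInsertionPlan(tinyBundle(), 12, seed = 102)
})

tinySample <- function() fixtureOnce("sample", {
  plantInsertions(tinyBundle(), tinyPlan(), nIndividuals = 10, seed = 103)
})

tinyWgs <- function() fixtureOnce("wgs", {
  simulateWGS(tinySample(), seqParams(depth = 15, seed = 104))
})

tinyAln <- function() fixtureOnce("aln", {
  alignReads(tinyWgs(), tinyBundle(), mode = "genome_split")
})

tinyLandscape <- function() fixtureOnce("landscape", {
  callInsertions(tinyAln(), tinyBundle(), sampleId = "tiny")
})

# a Landscape built directly from a calls table (no simulation)
makeLandscape <- function(calls, mapped = 1e6, id = "made") {
  defaults <- data.frame(chrom = "chr1", pos = 0, family = "TEfam1",
                         orientation = "+", iL = 2L, iR = 2L, i = 4L,
                         r = 0L, cr = 4, crClass = "gt2", category = "TE")
  for (col in names(defaults))
    if (is.null(calls[[col]]))
      calls[[col]] <- rep(defaults[[col]], length.out = nrow(calls))
  new("Landscape", sampleId = id, mappedReads = mapped, calls = calls)
}

# brute-force signed-rank p-value by full sign-pattern enumeration
enumSignedRank <- function(x, y = NULL, alternative = "two.sided") {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  pg <- mean(Ws >= W - 1e-9)
  pl <- mean(Ws <= W + 1e-9)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

# brute-force rank-sum p-value by enumeration of all group assignments
enumRankSum <- function(x, y, alternative = "two.sided") {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  Ws <- apply(combs, 2, function(ix) sum(r[ix]))
  pg <- mean(Ws >= W - 1e-9)
  pl <- mean(Ws <= W + 1e-9)
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}
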