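#' @include AllGenerics.R
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Simulate a PAE matrix with known ground truth
#'
#' Emulates the PAE signature of a modular protein with compact, mutually
#' separate domains, which is what the segmentation algorithm exploits:
#' residue pairs inside the same domain draw errors from uniform(0.5, 4)
#' Angstrom; pairs spanning two domains from uniform(15, 30); residues in
#' linkers or disordered termini are close only to their immediate sequence
#' neighbours (uniform(0.5, 4) for `|i - j| <= 2`, uniform(15, 30)
#' elsewhere). Gaussian noise of standard deviation `noiseSd` is added
#' independently per cell -- so the matrix is asymmetric and
#' [symmetrize()] is a load-bearing step -- values are clipped to
#' `[0, 31.75]` (the AlphaFold2 PAE ceiling) and the diagonal is zeroed.
#' The uniform ranges are chosen so the default 5-Angstrom contact
#' threshold separates intra-domain pairs from everything else with a noise
#' margin; lowering the inter-domain range toward 5-8 creates the
#' tightly-packed hard cases on which PAE-based segmentation is expected to
#' fail.
#'
#' Deterministic per `arch@seed`; the caller's RNG state is left untouched.
#'
#' @param arch an [Architecture-class].
#' @param noiseSd standard deviation (Angstrom) of the additive noise
#'   (default 0.5).
#' @param proteinId identifier for the generated chain.
#' @return A list with elements `pae` (a raw, unsymmetrized
#'   [PaeMatrix-class]) and `truth` (the exact [Segmentation-class] implied
#'   by `arch`).
#' @examples
#' sim <- generatePae(Architecture(c("domain", "linker", "domain"),
#'                                 c(150, 8, 120), seed = 7))
#' regionTable(sim$truth)
#' @export
generatePae <- function(arch, noiseSd = 0.5,
                        proteinId = sprintf("synth_%d", arch@seed)) {
  stopifnot(is(arch, "Architecture"))
  validObject(arch)
  el <- arch@elements
  L <- sum(el$length)
  kindPer <- rep(el$kind, el$length)
  # per-residue domain index; 0 for linker/disordered ("loose") residues
  domId <- rep(ifelse(el$kind == "domain", cumsum(el$kind == "domain"), 0L),
               el$length)
  idx <- seq_len(L)
  sameDomain <- outer(domId, domId, "==") & (domId > 0)
  looseNear <- (outer(domId == 0L, domId == 0L, "|")) &
               abs(outer(idx, idx, "-")) <= 2
  low <- sameDomain | looseNear
  m <- .withSeed(arch@seed, {
    m <- matrix(0, L, L)
    m[!low] <- stats::runif(sum(!low), 15, 30)
    m[low] <- stats::runif(sum(low), 0.5, 4)
    m + matrix(stats::rnorm(L * L, 0, noiseSd), L, L)
  })
  m <- pmin(pmax(m, 0), 31.75)
  diag(m) <- 0
  ends <- cumsum(el$length)
  truth <- Segmentation(proteinId, L,
                        start = ends - el$length + 1L, end = ends,
                        kind = ifelse(el$kind == "domain", "domain",
                               ifelse(el$kind == "linker", "linker",
                                      "disordered")))
  list(pae = PaeMatrix(m, proteinId = proteinId), truth = truth)
}

#' Sample a random lysin-like architecture
#'
#' Draws 1-4 domains (each 40-250 residues) joined by linkers of 3-20
#' residues; each terminus independently carries a disordered stretch of
#' 20-60 residues with probability 0.25. Deterministic per seed; the
#' caller's RNG state is left untouched.
#'
#' @param seed integer seed, also stored in the result for [generatePae()].
#' @return An [Architecture-class].
#' @export
randomArchitecture <- function(seed) {
  seed <- as.integer(seed)
  .withSeed(seed, {
    nDom <- sample.int(4L, 1L)
    domLens <- sample(40:250, nDom, replace = TRUE)
    linkLens <- if (nDom > 1L) sample(3:20, nDom - 1L, replace = TRUE)
                else integer(0)
    disN <- stats::runif(1) < 0.25
    disNLen <- if (disN) sample(20:60, 1L) else 0L
    disC <- stats::runif(1) < 0.25
    disCLen <- if (disC) sample(20:60, 1L) else 0L
    kind <- character(0); len <- integer(0)
    if (disN) { kind <- "disordered_n"; len <- disNLen }
    for (d in seq_len(nDom)) {
      kind <- c(kind, "domain"); len <- c(len, domLens[d])
      if (d < nDom) { kind <- c(kind, "linker"); len <- c(len, linkLens[d]) }
    }
    if (disC) { kind <- c(kind, "disordered_c"); len <- c(len, disCLen) }
    Architecture(kind, len, seed = seed)
  })
}
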