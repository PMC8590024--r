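# Synthetic-data generators with the statistical structure the analysis
# assumes: Balding-Nichols structured genotypes with injected sweeps,
# neutral coalescent haplotypes, negative-binomial reciprocal-transplant
# expression, toy gene models and diploid two-peak k-mer spectra.
#
# Every generator is a pure function of its arguments plus `seed`;
# independent components draw from offset seeds so adding one block never
# shifts another's stream.

#' Simulate structured diploid genotypes (Balding-Nichols)
#'
#' Per SNP an ancestral frequency p ~ Uniform(0.05, 0.95); each
#' population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with its own
#' divergence parameter F (F = 0 uses p exactly), and individual genotypes
#' are Binomial(2, p_pop). Optional sweep intervals override the target
#' population: SNP frequencies are pushed toward the fixation state
#' farther from the ancestral allele (creating a large frequency
#' differential against every other population), and a fraction of the
#' interval's SNPs is converted to singleton heterozygotes in the target
#' population (skewing its site-frequency spectrum toward rare variants).
#'
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param snpsPerChrom SNPs per chromosome (positions uniform, sorted).
#' @param popSizes named vector: diploid individuals per population.
#' @param Fst named vector of Balding-Nichols F per population (same names
#'   as `popSizes`; values in `[0, 1)`).
#' @param sweeps `NULL`, or data.frame with columns `chrom`, `start`,
#'   `end` (1-based closed), `target` (population label).
#' @param sweepFreq frequency the swept allele is pushed to (default
#'   0.99).
#' @param sweepSingletonFrac fraction of sweep-interval SNPs converted to
#'   target-population singletons (default 0.4).
#' @param seed integer seed (mandatory).
#' @return list: `gm` (a [GenotypeMatrix-class]), `truth` (data.frame of
#'   sweep intervals, or NULL), `freq` (matrix of per-population SNP
#'   frequencies as drawn).
#' @export
simGenotypes <- function(chromLengths, snpsPerChrom,
                         popSizes = c(NC = 30, MC = 30, SC = 30),
                         Fst = c(NC = 0.02, MC = 0.02, SC = 0.3),
                         sweeps = NULL, sweepFreq = 0.99,
                         sweepSingletonFrac = 0.4, seed) {
  stopifnot(!missing(seed), all(names(popSizes) %in% names(Fst)))
  if (any(Fst < 0 | Fst >= 1)) stop("Fst must lie in [0, 1)")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))

  set.seed(seed)
  chrom <- rep(names(chromLengths), each = snpsPerChrom)
  pos <- unlist(lapply(chromLengths, function(len)
    sort(sample.int(len, snpsPerChrom))), use.names = FALSE)
  nSnp <- length(pos)
  p <- runif(nSnp, 0.05, 0.95)
  pops <- names(popSizes)
  freq <- matrix(NA_real_, nSnp, length(pops),
                 dimnames = list(NULL, pops))
  for (k in pops) {
    Fk <- Fst[[k]]
    freq[, k] <- if (Fk == 0) p else
      rbeta(nSnp, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  geno <- matrix(NA_integer_, nSnp, sum(popSizes))
  popLab <- rep(pops, popSizes)
  col <- 1L
  for (k in pops) {
    for (i in seq_len(popSizes[[k]])) {
      geno[, col] <- rbinom(nSnp, 2L, freq[, k])
      col <- col + 1L
    }
  }
  colnames(geno) <- paste0(popLab, "_", unlist(lapply(popSizes, seq_len)))

  truth <- NULL
  if (!is.null(sweeps) && nrow(sweeps)) {
    set.seed(seed + 1000L)   # separate stream: sweeps never shift the rest
    for (r in seq_len(nrow(sweeps))) {
      tgt <- sweeps$target[r]
      tcols <- which(popLab == tgt)
      inSweep <- which(chrom == sweeps$chrom[r] &
                       pos >= sweeps$start[r] & pos <= sweeps$end[r])
      if (!length(inSweep)) next
      pushHigh <- p[inSweep] < 0.5
      pSwept <- ifelse(pushHigh, sweepFreq, 1 - sweepFreq)
      freq[inSweep, tgt] <- pSwept
      for (jj in seq_along(inSweep)) {
        geno[inSweep[jj], tcols] <- rbinom(length(tcols), 2L, pSwept[jj])
      }
      nSing <- round(sweepSingletonFrac * length(inSweep))
      if (nSing > 0) {
        singSites <- sample(inSweep, nSing)
        for (ss in singSites) {
          base <- as.integer(round(freq[ss, tgt]) * 2L)  # fixed state
          geno[ss, tcols] <- base
          geno[ss, sample(tcols, 1)] <- 1L               # one heterozygote
        }
      }
    }
    truth <- sweeps
  }
  gm <- GenotypeMatrix(geno, chrom, pos, populations = popLab)
  list(gm = gm, truth = truth, freq = freq)
}

#' Simulate neutral coalescent haplotypes (infinite sites)
#'
#' Standard constant-size neutral coalescent for a sample of `n`
#' haplotypes: while j lineages remain the next coalescence is exponential
#' with rate `choose(j, 2)`; mutations fall on branches as a Poisson
#' process of rate `theta / 2` per unit branch length, each creating a new
#' segregating site carried by the branch's descendants.
#'
#' @param n haplotypes per replicate (>= 2).
#' @param theta population mutation rate per locus.
#' @param nReps number of independent replicates.
#' @param seed integer seed.
#' @return list of 0/1 matrices (haplotypes x sites; 0 columns possible).
#' @export
simCoalescent <- function(n, theta, nReps, seed) {
  stopifnot(n >= 2, theta > 0)
  set.seed(seed)
  lapply(seq_len(nReps), function(rep) {
    members <- as.list(seq_len(n))   # active lineages: tip sets
    segLen <- numeric(0)
    segMembers <- list()
    j <- n
    while (j > 1) {
      t <- rexp(1, rate = j * (j - 1) / 2)
      # every active lineage gains a segment of length t
      segLen <- c(segLen, rep(t, j))
      segMembers <- c(segMembers, members)
      pick <- sample.int(j, 2)
      merged <- c(members[[pick[1]]], members[[pick[2]]])
      members <- c(members[-pick], list(merged))
      j <- j - 1
    }
    total <- sum(segLen)
    nMut <- rpois(1, theta / 2 * total)
    if (nMut == 0) return(matrix(0L, n, 0))
    seg <- sample.int(length(segLen), nMut, replace = TRUE,
                      prob = segLen)
    hap <- matrix(0L, n, nMut)
    for (m in seq_len(nMut)) hap[segMembers[[seg[m]]], m] <- 1L
    hap
  })
}

#' Simulate reciprocal-transplant expression counts
#'
#' Genes get log-normal baseline means and negative-binomial counts with a
#' common dispersion over a 2x2 design (population of origin N/S crossed
#' with habitat n/s, `reps` replicates per cell). A fraction of genes is
#' high-plasticity (HP): a habitat effect of |log2FC| = `log2fc` (random
#' sign, same in both populations). Of the remaining (LP) genes a fraction
#' carries the effect in one population only; the rest have none.
#' Per-sample depth factors are log-normal.
#'
#' @param nGenes number of genes.
#' @param reps replicates per population x habitat cell (>= 2).
#' @param hpFrac fraction of HP genes.
#' @param lpOneFrac fraction of LP genes with a single-population effect.
#' @param log2fc habitat-effect magnitude (log2).
#' @param dispersion NB dispersion (1/size).
#' @param baseMeanLog meanlog of the baseline expression distribution.
#' @param depthSd sdlog of the per-sample depth factors.
#' @param seed integer seed.
#' @return list: `ee` (an [ExpressionExperiment-class]), `truth`
#'   (data.frame gene/class/effect description).
#' @export
simExpression <- function(nGenes = 2000, reps = 5, hpFrac = 0.25,
                          lpOneFrac = 0.3, log2fc = 2, dispersion = 0.1,
                          baseMeanLog = log(100), depthSd = 0.2, seed) {
  stopifnot(reps >= 2)
  set.seed(seed)
  cells <- expand.grid(habitat = c("n", "s"), population = c("N", "S"),
                       stringsAsFactors = FALSE)[, c("population",
                                                     "habitat")]
  meta <- cells[rep(seq_len(nrow(cells)), each = reps), ]
  meta$replicate <- rep(seq_len(reps), times = nrow(cells))
  nSamp <- nrow(meta)

  base <- rlnorm(nGenes, meanlog = baseMeanLog, sdlog = 1)
  class <- rep("none", nGenes)
  nHp <- round(hpFrac * nGenes)
  class[seq_len(nHp)] <- "HP"
  lpIdx <- which(class == "none")
  nOne <- round(lpOneFrac * length(lpIdx))
  onePop <- sample(c("N", "S"), nOne, replace = TRUE)
  class[lpIdx[seq_len(nOne)]] <- paste0("one_", onePop)
  sign <- sample(c(-1, 1), nGenes, replace = TRUE)

  # log2 habitat effect (habitat s relative to n) per gene per population
  effN <- ifelse(class == "HP" | class == "one_N", sign * log2fc, 0)
  effS <- ifelse(class == "HP" | class == "one_S", sign * log2fc, 0)

  depth <- rlnorm(nSamp, 0, depthSd)
  counts <- matrix(0L, nGenes, nSamp)
  for (j in seq_len(nSamp)) {
    eff <- if (meta$population[j] == "N") effN else effS
    mu <- base * 2^(eff * (meta$habitat[j] == "s")) * depth[j]
    counts[, j] <- rnbinom(nGenes, mu = mu, size = 1 / dispersion)
  }
  rownames(counts) <- sprintf("g%05d", seq_len(nGenes))
  colnames(counts) <- paste0(meta$population, meta$habitat, "_",
                             meta$replicate)
  ee <- ExpressionExperiment(counts, meta$population, meta$habitat,
                             meta$replicate)
  truth <- data.frame(gene = rownames(counts),
                      class = ifelse(class == "HP", "HP", "LP"),
                      detail = class, effect_sign = sign,
                      stringsAsFactors = FALSE)
  list(ee = ee, truth = truth)
}

#' Simulate non-overlapping toy gene models
#'
#' @param nGenes genes per chromosome.
#' @param chromLengths named vector of chromosome lengths.
#' @param geneLength gene body length in bp.
#' @param minGap minimum spacing between genes (also from chromosome
#'   ends), keeping flanks disjoint.
#' @param seed integer seed.
#' @return `GRanges` with `gene_id` and random strand.
#' @export
simGeneModels <- function(nGenes, chromLengths, geneLength = 2000L,
                          minGap = 12000L, seed) {
  set.seed(seed)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  pitch <- geneLength + minGap
  pieces <- lapply(names(chromLengths), function(cc) {
    len <- chromLengths[[cc]]
    slots <- floor((len - minGap) / pitch)
    k <- min(nGenes, slots)
    at <- sort(sample.int(slots, k))
    starts <- minGap + (at - 1L) * pitch + 1L
    GRanges(cc, IRanges(starts, width = geneLength),
            strand = sample(c("+", "-"), k, replace = TRUE))
  })
  genes <- suppressWarnings(do.call(c, pieces))
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_along(genes))
  genes
}

#' Simulate a diploid two-peak k-mer spectrum
#'
#' An error spike at low depth plus two negative-binomial-shaped
#' components: a heterozygous single-copy peak with mode `hetDepth`
#' (default half the homozygous depth) and a homozygous peak with mode
#' `homDepth`. Non-error k-mer mass (`sum(depth * count)`) equals
#' `G * homDepth`; counts get Poisson sampling noise.
#'
#' @param G true genome size (bp).
#' @param homDepth homozygous single-copy peak depth (sequencing depth).
#' @param hetDepth heterozygous peak depth.
#' @param hetMassFrac fraction of non-error k-mer mass under the
#'   heterozygous component.
#' @param errRate scale of the error spike (0 disables it).
#' @param shape NB size parameter of the peak components (peak width).
#' @param seed integer seed.
#' @return list: `spectrum` (a [KmerSpectrum-class]), `G` (true size),
#'   `hom_depth`, `het_depth`.
#' @export
simKmerSpectrum <- function(G = 5e6, homDepth = 89L, hetDepth = NULL,
                            hetMassFrac = 0.3, errRate = 1,
                            shape = 30, seed) {
  stopifnot(homDepth > 5, G > 0)
  if (is.null(hetDepth)) hetDepth <- as.integer(round(homDepth / 2))
  set.seed(seed)
  depths <- seq_len(as.integer(round(3 * homDepth)))
  nbDens <- function(mode) {
    mu <- mode * shape / (shape - 1)   # put the NB mode at `mode`
    stats::dnbinom(depths, size = shape, mu = mu)
  }
  mass <- G * homDepth
  comp <- function(dens, m) m * dens / sum(depths * dens)
  counts <- comp(nbDens(hetDepth), hetMassFrac * mass) +
            comp(nbDens(homDepth), (1 - hetMassFrac) * mass)
  if (errRate > 0) {
    err <- errRate * G * exp(-1.5 * (depths - 1))
    err[depths > 8] <- 0
    counts <- counts + err
  }
  counts <- rpois(length(depths), counts)
  list(spectrum = KmerSpectrum(depths, counts), G = G,
       hom_depth = homDepth, het_depth = hetDepth)
}

#' Simulate per-gene region FST with an HP upstream shift
#'
#' Places HP and LP genes on one chromosome, partitions each into
#' upstream/genic/downstream via [partitionRegions()], scatters SNPs with
#' truncated-normal per-site FST in every region, adds `hpUpShift` to the
#' upstream SNPs of HP genes, and aggregates with [regionFst()] — the
#' ground-truth harness for the plasticity-divergence comparisons.
#'
#' @param nHp,nLp gene counts per class.
#' @param snpsPerRegion SNPs per region interval.
#' @param baseFst mean per-site FST of unshifted regions.
#' @param hpUpShift additive FST shift of HP upstream SNPs.
#' @param sdFst SNP-level FST standard deviation.
#' @param flank flank length (bp) for the partition.
#' @param seed integer seed.
#' @return list: `regionTable` (from [regionFst()]), `classes`
#'   (data.frame gene/class), `partitions`, `siteFst`.
#' @export
simRegionFst <- function(nHp = 200, nLp = 200, snpsPerRegion = 5,
                         baseFst = 0.74, hpUpShift = 0.05, sdFst = 0.15,
                         flank = 5000L, seed) {
  set.seed(seed)
  nG <- nHp + nLp
  pitch <- 2L * flank + 4000L
  chromLen <- (nG + 1L) * pitch
  starts <- flank + pitch * (seq_len(nG) - 1L) + 1L
  genes <- GRanges("chrS", IRanges(starts, width = 2000L),
                   strand = sample(c("+", "-"), nG, replace = TRUE))
  mcols(genes)$gene_id <- sprintf("gene%04d", seq_len(nG))
  classes <- data.frame(gene = genes$gene_id,
                        class = sample(rep(c("HP", "LP"), c(nHp, nLp))),
                        stringsAsFactors = FALSE)
  parts <- partitionRegions(genes, flank = flank,
                            chromLengths = c(chrS = chromLen))
  nP <- length(parts)
  pos <- unlist(lapply(seq_len(nP), function(i)
    sort(sample(start(parts)[i]:end(parts)[i], snpsPerRegion))))
  isHp <- classes$class[match(parts$gene_id, classes$gene)] == "HP"
  shift <- rep(ifelse(isHp & parts$region == "upstream", hpUpShift, 0),
               each = snpsPerRegion)
  fst <- pmin(1, pmax(0, rnorm(nP * snpsPerRegion, baseFst + shift,
                               sdFst)))
  o <- order(pos)
  siteFst <- GRanges("chrS", IRanges(pos[o], width = 1L), fst = fst[o])
  list(regionTable = regionFst(parts, siteFst), classes = classes,
       partitions = parts, siteFst = siteFst)
}
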