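# Conditional sampling of disease-locus inheritance given phenotypes,
# and the simulated-marker maximal-LOD power analysis built on it.

# Build the peeling trace at the disease locus only (trivial one-allele
# marker). Returns the schedule needed for top-down sampling.
disease_trace <- function(ped, model) {
  marker <- marker_locus("1", 1)
  hs <- hap_space(1L)
  pf <- hap_freqs(hs, model, marker$freqs)
  hp <- rep(seq_len(hs$H), each = hs$H); hm <- rep(seq_len(hs$H), hs$H)
  prior <- pf[hp] * pf[hm]
  fndr <- founders(ped)
  below <- setNames(vector("list", nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    b <- penetrance_vec(hs, model, ped$affection[i])
    if (ped$id[i] %in% fndr) b <- b * prior
    below[[ped$id[i]]] <- b
  }
  W <- gamete_matrix(hs, 0)
  out <- peel_likelihood(ped, below, W, trace = TRUE)
  if (out$likelihood <= 0)
    stop_input("phenotype configuration has zero likelihood under model")
  out$schedule <- lapply(out$schedule, function(e) {
    e$M <- Reduce(`*`, e$child_msgs)
    e
  })
  c(out, list(ped = ped, hs = hs, W = W))
}

sample_cat <- function(p) {
  # single draw from an unnormalized probability vector
  s <- sum(p)
  if (s <= 0) stop_input("conditional sampling hit a zero-mass state")
  sample.int(length(p), 1L, prob = p / s)
}

# One conditional draw of ordered disease diplotypes and gamete origin
# slots for every individual. Diplotype g in 1..4 encodes
# (paternal allele, maternal allele) with allele 2 = disease allele.
sample_inheritance_once <- function(tr) {
  ped <- tr$ped; H <- tr$hs$H; W <- tr$W
  g <- setNames(rep(NA_integer_, nrow(ped)), ped$id)
  origin <- list()
  sched <- rev(tr$schedule)
  sample_children <- function(entry, gf, gm) {
    fam <- entry$fam
    for (ci in seq_along(fam$children)) {
      cid <- fam$children[ci]
      bc <- entry$child_below[[cid]]
      hp <- rep(seq_len(H), each = H); hm <- rep(seq_len(H), H)
      pc <- W[gf, hp] * W[gm, hm] * bc
      gc <- sample_cat(pc)
      g[cid] <<- gc
      chp <- hp[gc]; chm <- hm[gc]
      fslots <- c((gf - 1L) %/% H + 1L, (gf - 1L) %% H + 1L)
      mslots <- c((gm - 1L) %/% H + 1L, (gm - 1L) %% H + 1L)
      pat <- which(fslots == chp)
      mat <- which(mslots == chm)
      origin[[cid]] <<- c(
        pat = if (length(pat) == 2L) sample.int(2L, 1L) else pat,
        mat = if (length(mat) == 2L) sample.int(2L, 1L) else mat)
    }
  }
  for (entry in sched) {
    fam <- entry$fam
    M <- entry$M
    if (length(entry$link) == 0L) {
      P <- outer(entry$bf, entry$bm) * M
      gfm <- sample_cat(as.vector(P))
      G <- H * H       # as.vector is column-major: index = (gm-1)*G + gf
      gm <- (gfm - 1L) %/% G + 1L
      gf <- (gfm - 1L) %% G + 1L
      g[fam$father] <- gf; g[fam$mother] <- gm
      sample_children(entry, gf, gm)
    } else if (entry$link == fam$father) {
      gf <- g[[fam$father]]
      stopifnot(!is.na(gf))
      gm <- sample_cat(entry$bm * M[gf, ])
      g[fam$mother] <- gm
      sample_children(entry, gf, gm)
    } else if (entry$link == fam$mother) {
      gm <- g[[fam$mother]]
      stopifnot(!is.na(gm))
      gf <- sample_cat(entry$bf * M[, gm])
      g[fam$father] <- gf
      sample_children(entry, gf, gm)
    } else {
      stop_input("conditional sampling requires families linked through ",
                 "a parent; reorder or simplify the pedigree")
    }
  }
  for (id in ped$id[is.na(g)]) {     # isolated individuals
    g[id] <- sample_cat(tr$below[[id]])
  }
  hpv <- (g - 1L) %/% H + 1L
  hmv <- (g - 1L) %% H + 1L
  list(pat_allele = setNames(hpv, ped$id),   # 1 wild, 2 disease
       mat_allele = setNames(hmv, ped$id),
       origin = origin)
}

#' Conditionally sample disease genotypes given phenotypes
#'
#' Draws ordered disease-locus genotypes (and, for non-founders, the
#' parental haplotype slot each gamete came from) from the exact
#' conditional distribution given all affection statuses under the
#' disease model. Used for gene dropping fully linked markers.
#'
#' @inheritParams pedigree_likelihood
#' @param n number of independent draws.
#' @param seed integer seed.
#' @return List of `n` draws; each has `pat_allele`/`mat_allele` (named
#'   vectors, 2 = disease allele) and `origin` (per non-founder, the
#'   father and mother haplotype slots transmitted).
#' @export
sample_disease_genotypes <- function(ped, model, n = 1, seed = 1) {
  tr <- disease_trace(ped, model)
  set.seed(derive_seed(seed, "sample_disease_genotypes"))
  replicate(n, sample_inheritance_once(tr), simplify = FALSE)
}

# Drop marker alleles through sampled inheritance. founder_slots is a
# named list of length-2 vectors of allele labels per founder.
drop_marker <- function(ped, draw, founder_slots) {
  alleles <- list()
  remaining <- ped$id
  while (length(remaining) > 0L) {
    progressed <- FALSE
    for (id in remaining) {
      i <- match(id, ped$id)
      if (is.na(ped$father[i])) {
        alleles[[id]] <- founder_slots[[id]]
        remaining <- setdiff(remaining, id); progressed <- TRUE
      } else if (!is.null(alleles[[ped$father[i]]]) &&
                 !is.null(alleles[[ped$mother[i]]])) {
        o <- draw$origin[[id]]
        alleles[[id]] <- c(alleles[[ped$father[i]]][o[["pat"]]],
                           alleles[[ped$mother[i]]][o[["mat"]]])
        remaining <- setdiff(remaining, id); progressed <- TRUE
      }
    }
    if (!progressed) stop_input("pedigree is not topologically orderable")
  }
  alleles
}

#' Maximal LOD by simulation of fully linked markers
#'
#' Estimates the power of a pedigree as the maximal parametric LOD score
#' attainable with markers completely linked to the disease locus:
#' disease-locus inheritance is sampled conditional on the phenotypes,
#' a marker is gene-dropped along the sampled transmissions at
#' `theta = 0`, observation is restricted to `typed_ids`, and the LOD is
#' maximized over the recombination-fraction grid for every replicate.
#' With the default fully informative marker (two unique equifrequent
#' alleles per founder) the maximum equals
#' [informative_meioses()]` * log10(2)` for a fully penetrant dominant
#' model.
#'
#' @inheritParams pedigree_likelihood
#' @param typed_ids ids with marker genotypes available.
#' @param n_markers number of simulated markers (replicates).
#' @param seed integer seed; governs all replicates.
#' @param theta_grid grid over which each replicate's LOD is maximized.
#' @param marker_type `"fully_informative"` (default) or `"biallelic"`
#'   (two alleles at frequency 0.5).
#' @param condition `"genotypes"` (default) scores each simulated marker
#'   against the simulated disease-locus inheritance itself (disease
#'   genotypes of all members treated as observed), so that with fully
#'   informative markers the maximum equals the analytic
#'   `informative_meioses() * log10(2)`; `"phenotypes"` marginalizes the
#'   disease genotypes given only the affection statuses, in which case
#'   the phenocopy rate f0 slightly depresses the maximum (order
#'   `f0 / ln 10`).
#' @return Object of class `lod_power`: list with `max_lod`, per-replicate
#'   `lods`, `n_markers`, and the number of distinct marker datasets
#'   evaluated.
#' @export
max_lod_power <- function(ped, model, typed_ids, n_markers = 10000,
                          seed = 1, theta_grid = seq(0, 0.5, by = 0.01),
                          marker_type = c("fully_informative", "biallelic"),
                          condition = c("genotypes", "phenotypes")) {
  marker_type <- match.arg(marker_type)
  condition <- match.arg(condition)
  if (length(typed_ids) == 0L) stop_input("typed_ids must be non-empty")
  if (!all(typed_ids %in% ped$id))
    stop_input("typed_ids must be pedigree members")
  if (n_markers < 1L) stop_input("n_markers must be >= 1")
  tr <- disease_trace(ped, model)
  fndr <- founders(ped)
  nf <- length(fndr)
  set.seed(derive_seed(seed, "max_lod_power"))
  cache <- new.env(parent = emptyenv())
  lods <- numeric(n_markers)
  for (r in seq_len(n_markers)) {
    draw <- sample_inheritance_once(tr)
    founder_slots <- if (marker_type == "fully_informative") {
      setNames(lapply(seq_len(nf), function(j) c(2L * j - 1L, 2L * j)),
               fndr)
    } else {
      setNames(lapply(seq_len(nf), function(j)
        sample.int(2L, 2L, replace = TRUE)), fndr)
    }
    alleles <- drop_marker(tr$ped, draw, founder_slots)
    obs <- lapply(typed_ids, function(id) sort(alleles[[id]]))
    dis <- if (condition == "genotypes") {
      setNames((draw$pat_allele == 2L) + (draw$mat_allele == 2L),
               names(draw$pat_allele))
    } else NULL
    # canonical relabeling in order of first appearance; the likelihood
    # is invariant under allele permutation (equifrequent alleles)
    seen <- unique(unlist(obs))
    relab <- setNames(seq_along(seen), seen)
    key <- paste(
      paste(vapply(obs, function(ab)
        paste(sort(relab[as.character(ab)]), collapse = "/"), character(1)),
        collapse = ";"),
      if (is.null(dis)) "" else paste(dis, collapse = ""), sep = "|")
    if (is.null(cache[[key]])) {
      n_all <- if (marker_type == "fully_informative") 2L * nf else 2L
      n_obs <- length(seen)
      k <- min(n_obs + 1L, n_all)
      freqs <- rep(1 / n_all, k)
      if (k > n_obs) freqs[k] <- (n_all - n_obs) / n_all
      genos <- setNames(vapply(obs, function(ab)
        paste(sort(relab[as.character(ab)]), collapse = "/"), character(1)),
        typed_ids)
      mk <- marker_locus(as.character(seq_len(k)), freqs, genos)
      cache[[key]] <- lod_score(tr$ped, model, mk, theta_grid,
                                dis_dosage = dis)$max_lod
    }
    lods[r] <- cache[[key]]
  }
  structure(list(max_lod = max(lods), lods = lods, n_markers = n_markers,
                 n_distinct = length(ls(cache)), typed_ids = typed_ids,
                 marker_type = marker_type),
            class = "lod_power")
}

#' @export
print.lod_power <- function(x, ...) {
  cat(sprintf(
    "Maximal LOD over %d simulated fully linked markers (%s): %.5f\n",
    x$n_markers, x$marker_type, x$max_lod))
  invisible(x)
}

#' Restrict variants to genomic intervals
#'
#' Keeps variants whose position falls inside any of the supplied
#' 1-based inclusive intervals (e.g. maximal-LOD linkage regions or
#' shared haplotype regions).
#'
#' @param variants data frame with columns `chrom` and `pos`.
#' @param regions data frame with columns `chrom`, `start`, `end`.
#' @return Logical vector marking variants inside a region.
#' @export
region_intersect <- function(variants, regions) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)),
            all(c("chrom", "start", "end") %in% names(regions)))
  vapply(seq_len(nrow(variants)), function(i) {
    any(regions$chrom == variants$chrom[i] &
          regions$start <= variants$pos[i] &
          regions$end >= variants$pos[i])
  }, logical(1))
}
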