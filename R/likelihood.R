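#' Single-locus dominant disease model
#'
#' @param freq disease allele frequency in (0, 1).
#' @param f0,f1,f2 penetrances: probability of the affected phenotype
#'   given 0, 1 or 2 copies of the disease allele, each in \[0, 1\].
#' @return An object of class `disease_model`.
#' @examples
#' disease_model(0.0001, 0.0001, 1, 1)  # rare fully penetrant dominant
#' @export
disease_model <- function(freq, f0, f1, f2) {
  stopifnot(freq > 0, freq < 1,
            all(c(f0, f1, f2) >= 0), all(c(f0, f1, f2) <= 1))
  structure(list(freq = freq, penetrances = c(f0 = f0, f1 = f1, f2 = f2)),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("Disease model: allele freq %g, penetrances (%g, %g, %g)\n",
              x$freq, x$penetrances[1], x$penetrances[2], x$penetrances[3]))
  invisible(x)
}

#' Marker locus with per-individual genotypes
#'
#' @param alleles character vector of allele labels.
#' @param freqs positive allele frequencies summing to 1 (within 1e-9).
#' @param genotypes named character vector of unordered marker genotypes
#'   `"a/b"` over the allele labels; `NA` or omission = untyped.
#' @return An object of class `marker_locus`.
#' @export
marker_locus <- function(alleles, freqs, genotypes = character()) {
  stopifnot(length(alleles) == length(freqs), all(freqs > 0))
  if (abs(sum(freqs) - 1) > 1e-9)
    stop_input("marker allele frequencies must sum to 1")
  genotypes <- genotypes[!is.na(genotypes)]
  if (length(genotypes) > 0L) {
    parts <- strsplit(genotypes, "/", fixed = TRUE)
    if (any(lengths(parts) != 2L) ||
        !all(unlist(parts) %in% alleles))
      stop_input("marker genotypes must be 'a/b' over the allele labels")
  }
  structure(list(alleles = as.character(alleles), freqs = freqs,
                 genotypes = genotypes),
            class = "marker_locus")
}

# ---- internal two-locus state space -----------------------------------
# haplotype h = (d - 1) * k + m, d in 1:2 (2 = disease allele), m in 1:k
# ordered diplotype g = (hp - 1) * H + hm  (paternal, maternal)

hap_space <- function(k) {
  H <- 2L * k
  list(k = k, H = H, G = H * H,
       d = rep(1:2, each = k), m = rep(seq_len(k), 2L))
}

gamete_matrix <- function(hs, theta) {
  # W[g, h] = P(gamete haplotype h | parent ordered diplotype g)
  H <- hs$H
  W <- matrix(0, nrow = hs$G, ncol = H)
  for (hp in seq_len(H)) for (hm in seq_len(H)) {
    g <- (hp - 1L) * H + hm
    W[g, hp] <- W[g, hp] + (1 - theta) / 2
    W[g, hm] <- W[g, hm] + (1 - theta) / 2
    r1 <- (hs$d[hp] - 1L) * hs$k + hs$m[hm]
    r2 <- (hs$d[hm] - 1L) * hs$k + hs$m[hp]
    W[g, r1] <- W[g, r1] + theta / 2
    W[g, r2] <- W[g, r2] + theta / 2
  }
  W
}

hap_freqs <- function(hs, model, marker_freqs) {
  q <- c(1 - model$freq, model$freq)
  q[hs$d] * marker_freqs[hs$m]
}

diplo_index <- function(hs, hp, hm) (hp - 1L) * hs$H + hm

ndis_vec <- function(hs) {
  hp <- rep(seq_len(hs$H), each = hs$H)
  hm <- rep(seq_len(hs$H), times = hs$H)
  (hs$d[hp] == 2L) + (hs$d[hm] == 2L)
}

penetrance_vec <- function(hs, model, affection) {
  nd <- ndis_vec(hs)
  f <- model$penetrances
  switch(affection,
         affected = f[nd + 1L],
         unaffected = 1 - f[nd + 1L],
         unknown = rep(1, hs$G))
}

marker_obs_vec <- function(hs, geno, alleles) {
  # geno: "a/b" or NA; 1 iff unordered marker pair matches
  if (is.na(geno)) return(rep(1, hs$G))
  ab <- match(strsplit(geno, "/", fixed = TRUE)[[1]], alleles)
  hp <- rep(seq_len(hs$H), each = hs$H)
  hm <- rep(seq_len(hs$H), times = hs$H)
  mp <- hs$m[hp]; mm <- hs$m[hm]
  as.numeric((mp == ab[1] & mm == ab[2]) | (mp == ab[2] & mm == ab[1]))
}

ped_families <- function(ped) {
  nf <- which(!is.na(ped$father))
  if (length(nf) == 0L) return(list())
  key <- paste(ped$father[nf], ped$mother[nf])
  lapply(split(nf, key), function(rows) {
    list(father = ped$father[rows[1]], mother = ped$mother[rows[1]],
         children = ped$id[rows])
  })
}

# Generic likelihood by peeling over nuclear families. Supports any
# loop-free pedigree (including multiple marriages and marriages between
# members of disjoint sub-ancestries). If `trace = TRUE`, records the
# peeling schedule and messages needed for conditional sampling.
peel_likelihood <- function(ped, below, W, trace = FALSE) {
  fams <- ped_families(ped)
  in_family <- function(id, fam)
    id == fam$father || id == fam$mother || id %in% fam$children
  active <- rep(TRUE, length(fams))
  total <- 1
  sched <- list()
  members_of <- function(fam) c(fam$father, fam$mother, fam$children)

  while (any(active)) {
    # candidates: families sharing at most one member with the rest;
    # prefer absorbing into a parent (keeps the schedule usable for
    # top-down conditional sampling), fall back to a child link
    picked <- NA_integer_
    link <- NULL
    fallback <- NULL
    for (i in which(active)) {
      others <- unlist(lapply(setdiff(which(active), i),
                              function(j) members_of(fams[[j]])))
      shared <- intersect(members_of(fams[[i]]), others)
      if (length(shared) > 1L) next
      if (length(shared) == 0L ||
          shared %in% c(fams[[i]]$father, fams[[i]]$mother)) {
        picked <- i; link <- shared; break
      }
      if (is.null(fallback)) fallback <- list(i = i, link = shared)
    }
    if (is.na(picked) && !is.null(fallback)) {
      picked <- fallback$i; link <- fallback$link
    }
    if (is.na(picked))
      stop_input("pedigree contains loops; peeling order not found")
    fam <- fams[[picked]]
    H <- ncol(W)
    bf <- below[[fam$father]]; bm <- below[[fam$mother]]
    child_msgs <- lapply(fam$children, function(c) {
      Phi <- matrix(below[[c]], nrow = H, byrow = TRUE) # [hp, hm]
      W %*% Phi %*% t(W)
    })
    M <- Reduce(`*`, child_msgs)
    if (length(link) == 0L) {
      total <- total * as.numeric(t(bf) %*% M %*% bm)
    } else if (link == fam$father) {
      below[[fam$father]] <- bf * as.numeric(M %*% bm)
    } else if (link == fam$mother) {
      below[[fam$mother]] <- bm * as.numeric(crossprod(M, bf))
    } else {
      # link is a child: push an anterior message down to it
      c0 <- link
      others <- child_msgs[fam$children != c0]
      Q <- outer(bf, bm) * Reduce(`*`, others, init = 1)
      A <- t(W) %*% Q %*% W                  # [hp, hm]
      # A[hp, hm] marginalizes parents and sibs against P(g_c | parents)
      below[[c0]] <- below[[c0]] * as.vector(t(A))
    }
    if (trace)
      sched[[length(sched) + 1L]] <-
        list(fam = fam, link = link, bf = bf, bm = bm,
             child_msgs = child_msgs,
             child_below = setNames(below[fam$children], fam$children))
    active[picked] <- FALSE
  }
  solo <- setdiff(ped$id, unlist(lapply(fams, members_of)))
  for (id in solo) total <- total * sum(below[[id]])
  if (trace) list(likelihood = total, schedule = sched, below = below)
  else total
}

#' Exact two-locus pedigree likelihood
#'
#' Probability of the observed affection statuses and marker genotypes
#' given the pedigree, a single-locus disease model and the recombination
#' fraction between disease and marker locus, computed exactly by
#' Elston-Stewart-style peeling over nuclear families (loop-free
#' pedigrees). Founder diplotypes follow Hardy-Weinberg and linkage
#' equilibrium; marker genotypes are unordered and may be missing.
#'
#' @param ped a [pedigree()]; affection statuses are read from it,
#'   `"unknown"` phenotypes are marginalized.
#' @param model a [disease_model()].
#' @param marker a [marker_locus()]; individuals absent from
#'   `marker$genotypes` are untyped. `NULL` for a phenotype-only
#'   likelihood.
#' @param theta recombination fraction in \[0, 0.5\].
#' @param dis_dosage optional named integer vector of observed
#'   disease-allele counts (0/1/2) per individual; listed individuals
#'   have their disease genotype conditioned on in addition to the
#'   phenotype. Used to score markers against a known disease-locus
#'   inheritance, as in simulation-based power analysis.
#' @return The likelihood, a probability in \[0, 1\]; 0 when the marker
#'   data are Mendelianly impossible.
#' @export
pedigree_likelihood <- function(ped, model, marker = NULL, theta = 0,
                                dis_dosage = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 0.5)
    stop_input("theta must be a single value in [0, 0.5]")
  if (is.null(marker))
    marker <- marker_locus("1", 1)
  bad <- setdiff(names(marker$genotypes), ped$id)
  if (length(bad) > 0L)
    stop_input("marker genotypes for unknown individuals: ",
               paste(bad, collapse = ", "))
  hs <- hap_space(length(marker$alleles))
  pf <- hap_freqs(hs, model, marker$freqs)
  # ordered diplotype prior: p(hp) * p(hm) with g = (hp-1)*H + hm
  hp <- rep(seq_len(hs$H), each = hs$H); hm <- rep(seq_len(hs$H), hs$H)
  prior <- pf[hp] * pf[hm]
  fndr <- founders(ped)
  nd <- ndis_vec(hs)
  below <- setNames(vector("list", nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    b <- penetrance_vec(hs, model, ped$affection[i])
    geno <- if (id %in% names(marker$genotypes)) marker$genotypes[[id]]
            else NA_character_
    b <- b * marker_obs_vec(hs, geno, marker$alleles)
    if (!is.null(dis_dosage) && id %in% names(dis_dosage))
      b <- b * as.numeric(nd == dis_dosage[[id]])
    if (id %in% fndr) b <- b * prior
    below[[id]] <- b
  }
  W <- gamete_matrix(hs, theta)
  peel_likelihood(ped, below, W)
}

#' LOD scores over a recombination-fraction grid
#'
#' `LOD(theta) = log10 L(theta) - log10 L(0.5)`: the standard parametric
#' linkage statistic comparing complete or partial linkage against free
#' recombination.
#'
#' @inheritParams pedigree_likelihood
#' @param theta_grid recombination fractions to evaluate; 0.5 is always
#'   appended if absent.
#' @return An object of class `linkage_result`: list with `theta`,
#'   `lod` and `max_lod`.
#' @export
lod_score <- function(ped, model, marker,
                      theta_grid = seq(0, 0.5, by = 0.01),
                      dis_dosage = NULL) {
  theta_grid <- sort(unique(c(theta_grid, 0.5)))
  L <- vapply(theta_grid, function(th)
    pedigree_likelihood(ped, model, marker, th, dis_dosage = dis_dosage),
    numeric(1))
  L_half <- L[length(L)]
  if (L_half <= 0)
    stop_input("data impossible under free recombination (L(0.5) = 0)")
  lod <- log10(L / L_half)
  structure(list(theta = theta_grid, lod = lod, max_lod = max(lod)),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("LOD over %d theta values; max LOD = %.5f at theta = %g\n",
              length(x$theta), x$max_lod,
              x$theta[which.max(x$lod)]))
  invisible(x)
}
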