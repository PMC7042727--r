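# Genotype calls are compact strings over {0 = ref, 1 = alt, . = missing},
# e.g. "0/1", "./.", "0/."; the companion quality flag is one of
# "VQHIGH", "low", "nocall". A call is a full no-call iff both alleles
# are missing, in which case the quality flag must be "nocall".

GT_NOCALL <- "./."

gt_split <- function(gt) {
  m <- matrix(unlist(strsplit(gt, "/", fixed = TRUE), use.names = FALSE),
              ncol = 2L, byrow = TRUE)
  m[m == "."] <- NA_character_
  m
}

gt_norm <- function(gt) {
  # unordered: sort alleles, missing last
  m <- gt_split(gt)
  a <- ifelse(is.na(m[, 1]), ".", m[, 1])
  b <- ifelse(is.na(m[, 2]), ".", m[, 2])
  swap <- (a > b & b != ".") | (a == "." & b != ".")
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "/")
}

gt_is_het <- function(gt) gt_norm(gt) == "0/1"
gt_is_homref <- function(gt) gt_norm(gt) == "0/0"
gt_is_nocall <- function(gt) gt_norm(gt) == "./."
gt_has_missing <- function(gt) {
  m <- gt_split(gt)
  is.na(m[, 1]) | is.na(m[, 2])
}

gt_dosage <- function(gt) {
  # alt-allele count; NA for any half- or no-call
  m <- gt_split(gt)
  out <- as.integer(m[, 1] == "1") + as.integer(m[, 2] == "1")
  out[is.na(m[, 1]) | is.na(m[, 2])] <- NA_integer_
  out
}

#' Flag Mendelian-inconsistent trios at a single site
#'
#' For each individual with both parents in the pedigree, the trio is
#' flagged iff the child's called alleles are impossible under Mendelian
#' transmission from the parents' called genotypes. Missing alleles
#' (half-calls and no-calls) are compatible with anything, so a trio with
#' any missing allele in it is never flagged.
#'
#' @param ped a [pedigree()].
#' @param genotypes named character vector of genotype strings
#'   (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`, ...), named by individual id.
#'   Individuals absent from the vector are treated as untyped.
#' @return Character vector of child ids whose trio is inconsistent.
#' @export
mendelian_check <- function(ped, genotypes) {
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop_input("genotypes must be a named vector")
  unknown <- setdiff(names(genotypes), ped$id)
  if (length(unknown) > 0L)
    stop_input("unknown individual id(s) in genotypes: ",
               paste(unknown, collapse = ", "))
  gt_of <- function(id) {
    if (id %in% names(genotypes)) genotypes[[id]] else GT_NOCALL
  }
  flagged <- character()
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i]) || is.na(ped$mother[i])) next
    child <- gt_of(ped$id[i])
    fa <- gt_of(ped$father[i])
    mo <- gt_of(ped$mother[i])
    if (!gt_compatible(child, fa, mo)) flagged <- c(flagged, ped$id[i])
  }
  flagged
}

gt_compatible <- function(child, father, mother) {
  cm <- gt_split(child); fm <- gt_split(father); mm <- gt_split(mother)
  # half- and no-called children are never flagged (conservative)
  if (anyNA(cm)) return(TRUE)
  trans <- function(p) { a <- p[!is.na(p)]; if (length(a) < 2L) c(a, "0", "1") else a }
  tf <- unique(trans(fm[1, ])); tm <- unique(trans(mm[1, ]))
  c1 <- cm[1, 1]; c2 <- cm[1, 2]
  for (x in tf) for (y in tm) {
    ok1 <- (is.na(c1) || c1 == x) && (is.na(c2) || c2 == y)
    ok2 <- (is.na(c1) || c1 == y) && (is.na(c2) || c2 == x)
    if (ok1 || ok2) return(TRUE)
  }
  FALSE
}

#' Method-of-moments kinship estimation from biallelic genotypes
#'
#' Standardizes each genotype by its population allele frequency and
#' averages cross-products over sites, yielding pairwise kinship
#' coefficients: ~0.5 on the diagonal for a non-inbred individual, ~0.25
#' for parent-offspring or full sibs, ~0 for unrelateds. Half-called and
#' missing genotypes are excluded pairwise.
#'
#' @param genotypes numeric matrix of alt-allele dosages (0/1/2, `NA`
#'   allowed), sites in rows, individuals in columns.
#' @param freqs per-site alt allele frequencies in (0, 1); sites at the
#'   boundary are dropped.
#' @return Symmetric kinship matrix over individuals.
#' @export
kinship_estimate <- function(genotypes, freqs) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(freqs))
  keep <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(keep))
    stop_input("kinship estimator undefined: no polymorphic sites")
  g <- genotypes[keep, , drop = FALSE]
  p <- freqs[keep]
  x <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  num <- crossprod(x0)
  den <- crossprod(obs * 1)          # pairwise complete site counts
  if (any(den == 0))
    stop_input("kinship estimator undefined: a pair has no complete sites")
  k <- num / den / 2
  dimnames(k) <- list(colnames(genotypes), colnames(genotypes))
  k
}

#' Count phase-resolvable informative meioses
#'
#' Counts transmissions from a genotyped carrier parent to a genotyped
#' offspring whose disease-locus carrier status is determined by
#' phenotype (affected => carrier, unaffected => non-carrier under a
#' fully penetrant dominant model; unknown phenotype => undetermined).
#' One meiosis is discounted for each carrier parent whose own linkage
#' phase cannot be anchored (no typed carrier parent of their own): the
#' first scored transmission of such a parent establishes phase instead
#' of testing it. Under a fully penetrant dominant model the maximal
#' attainable LOD with fully informative markers is
#' `count * log10(2)`; see [max_lod_power()].
#'
#' @param ped a [pedigree()].
#' @param carriers character vector of obligate carrier ids.
#' @param typed character vector of genotyped ids.
#' @return Integer count of phase-resolvable transmissions.
#' @export
informative_meioses <- function(ped, carriers, typed) {
  if (!all(carriers %in% ped$id))
    stop_input("carriers must be pedigree members")
  determined <- ped$id[ped$affection != "unknown"]
  total <- 0L
  for (p in intersect(carriers, typed)) {
    i <- match(p, ped$id)
    kids <- ped$id[!is.na(ped$father) & ped$father == p |
                   !is.na(ped$mother) & ped$mother == p]
    scored <- intersect(intersect(kids, typed), determined)
    if (length(scored) == 0L) next
    parents <- c(ped$father[i], ped$mother[i])
    phase_known <- any(!is.na(parents) &
                         parents %in% intersect(carriers, typed))
    total <- total + length(scored) - if (phase_known) 0L else 1L
  }
  total
}
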