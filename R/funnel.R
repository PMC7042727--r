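# The staged variant-prioritization funnel: union of per-genome calls,
# genotype-quality filter, shared-haplotype restriction, dominant
# segregation, population rarity, functional class, gene-list membership,
# pathogenicity voting and candidate-gene prioritization, with a
# per-stage audit report.

#' Variant call-set container
#'
#' Holds a set of variant sites with per-individual genotype calls and
#' quality flags. Genotypes are strings over `{0, 1, .}` (`"0/1"`,
#' `"./."`, ...); quality flags are `"VQHIGH"`, `"low"` or `"nocall"`.
#'
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param gt character matrix `n_variants x n_individuals` of genotype
#'   strings; column names are individual ids.
#' @param qual character matrix of the same shape with quality flags.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, gt, qual) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            is.matrix(gt), is.matrix(qual),
            nrow(gt) == nrow(variants), identical(dim(gt), dim(qual)),
            !is.null(colnames(gt)))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  if (anyDuplicated(key))
    stop_input("duplicate variant keys in call set")
  if (length(gt) > 0L && any(gt_is_nocall(c(gt)) != (c(qual) == "nocall")))
    stop_input("quality flag 'nocall' must coincide with genotype './.'")
  variants$key <- key
  structure(list(variants = variants, gt = gt, qual = qual,
                 individuals = colnames(gt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants x %d individuals\n",
              nrow(x$variants), length(x$individuals)))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$variants)

subset_variants <- function(vs, keep) {
  variant_set(vs$variants[keep, c("chrom", "pos", "ref", "alt"),
                          drop = FALSE],
              vs$gt[keep, , drop = FALSE],
              vs$qual[keep, , drop = FALSE])
}

#' Funnel configuration
#'
#' Thresholds and id sets driving [run_funnel()] and the individual
#' filter stages. Defaults follow the published pipeline: population
#' allele frequency at or below 1%, at least 5 of the 8 pathogenicity
#' predictors deleterious and at least 2 of the 4 conservation scores
#' conserved, IBS windows of 100 sites tolerating 2% zero-IBS sites.
#'
#' @param max_pop_freq maximum population allele frequency (inclusive).
#' @param min_deleterious minimum deleterious pathogenicity calls.
#' @param min_conserved minimum conserved conservation calls.
#' @param case_ids,control_ids disjoint individual id sets for the
#'   dominant-segregation filter.
#' @param window_size IBS scan window, in mutually called sites.
#' @param max_mismatch_frac maximum fraction of zero-IBS sites per
#'   window.
#' @param control_nocall_rescue if `TRUE`, a control no-call does not
#'   disqualify a variant (the laxer reading of "not called in any
#'   control"); default `FALSE`: every control must be called
#'   homozygous reference.
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(max_pop_freq = 0.01, min_deleterious = 5L,
                          min_conserved = 2L, case_ids = character(),
                          control_ids = character(), window_size = 100L,
                          max_mismatch_frac = 0.02,
                          control_nocall_rescue = FALSE) {
  stopifnot(max_pop_freq > 0, max_pop_freq <= 1,
            min_deleterious >= 0, min_conserved >= 0,
            window_size >= 1, max_mismatch_frac >= 0,
            max_mismatch_frac <= 1)
  if (length(intersect(case_ids, control_ids)) > 0L)
    stop_input("case_ids and control_ids must be disjoint")
  structure(list(max_pop_freq = max_pop_freq,
                 min_deleterious = as.integer(min_deleterious),
                 min_conserved = as.integer(min_conserved),
                 case_ids = case_ids, control_ids = control_ids,
                 window_size = as.integer(window_size),
                 max_mismatch_frac = max_mismatch_frac,
                 control_nocall_rescue = control_nocall_rescue),
            class = "funnel_config")
}

#' Union of per-genome variant lists
#'
#' Combines per-individual call lists into one call set keyed by
#' (chrom, pos, ref, alt). Sites at which an individual reported no
#' variant receive a no-call, mirroring the union-then-test approach of
#' combining single-genome variant files.
#'
#' @param call_lists named list (by individual id) of data frames with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gt`, `qual`.
#' @return A [variant_set()] over all individuals.
#' @export
union_variants <- function(call_lists) {
  if (length(call_lists) == 0L || all(vapply(call_lists, nrow, 1L) == 0L)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    ids <- names(call_lists) %||% character()
    gt <- matrix(character(), 0, length(ids),
                 dimnames = list(NULL, ids))
    return(variant_set(empty, gt, gt))
  }
  if (is.null(names(call_lists)) || anyDuplicated(names(call_lists)))
    stop_input("call_lists must be uniquely named by individual id")
  all <- data.table::rbindlist(
    lapply(names(call_lists), function(id) {
      d <- data.table::as.data.table(call_lists[[id]])
      d[, `:=`(indiv = id)]
      d
    }))
  all[, key := variant_key(chrom, pos, ref, alt)]
  # conflicting REF at identical position is a data error
  refs <- unique(all[, .(chrom, pos, ref)])
  dup <- refs[duplicated(refs[, .(chrom, pos)])]
  if (nrow(dup) > 0L)
    stop_input("conflicting REF alleles at ",
               paste(dup$chrom, dup$pos, sep = ":", collapse = ", "))
  sites <- unique(all[, .(chrom, pos, ref, alt, key)])
  data.table::setorder(sites, chrom, pos, alt)
  ids <- names(call_lists)
  gt <- matrix(GT_NOCALL, nrow(sites), length(ids),
               dimnames = list(NULL, ids))
  qual <- matrix("nocall", nrow(sites), length(ids),
                 dimnames = list(NULL, ids))
  ridx <- match(all$key, sites$key)
  cidx <- match(all$indiv, ids)
  gt[cbind(ridx, cidx)] <- all$gt
  qual[cbind(ridx, cidx)] <- all$qual
  variant_set(as.data.frame(sites[, .(chrom, pos, ref, alt)]), gt, qual)
}

#' Genotype-quality filter
#'
#' Keeps variants called at high quality (`VQHIGH`) in at least one
#' individual.
#'
#' @param vs a [variant_set()].
#' @return Filtered [variant_set()] with attribute `removed` (count).
#' @export
quality_filter <- function(vs) {
  keep <- apply(vs$qual == "VQHIGH", 1, any)
  out <- subset_variants(vs, keep)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Dominant-segregation filter
#'
#' A variant survives iff every case is heterozygous for the alternate
#' allele or has a (half- or no-)call, at least one case is called
#' heterozygous, and every control is called homozygous reference. With
#' `control_nocall_rescue = TRUE` in the config a control no-call is
#' tolerated instead.
#'
#' @param vs a [variant_set()].
#' @param case_ids,control_ids disjoint non-empty id sets.
#' @param control_nocall_rescue see [funnel_config()].
#' @return Filtered [variant_set()].
#' @export
dominant_filter <- function(vs, case_ids, control_ids,
                            control_nocall_rescue = FALSE) {
  if (length(case_ids) == 0L || length(control_ids) == 0L)
    stop_input("case and control sets must be non-empty")
  if (length(intersect(case_ids, control_ids)) > 0L)
    stop_input("an individual appears in both case and control sets")
  missing_ids <- setdiff(c(case_ids, control_ids), vs$individuals)
  if (length(missing_ids) > 0L)
    stop_input("ids without calls: ", paste(missing_ids, collapse = ", "))
  case_gt <- vs$gt[, case_ids, drop = FALSE]
  ctrl_gt <- vs$gt[, control_ids, drop = FALSE]
  case_ok <- apply(case_gt, 1, function(g)
    all(gt_is_het(g) | gt_has_missing(g)) && any(gt_is_het(g)))
  ctrl_ok <- apply(ctrl_gt, 1, function(g) {
    if (control_nocall_rescue) all(gt_is_homref(g) | gt_has_missing(g))
    else all(gt_is_homref(g))
  })
  subset_variants(vs, case_ok & ctrl_ok)
}

#' Population-rarity filter
#'
#' A variant survives iff every available population allele frequency is
#' at or below `max_pop_freq` ("equal or <1%"); variants with no
#' frequency record are treated as rare and kept.
#'
#' @param vs a [variant_set()].
#' @param annotations annotation table, see [read_annotations()].
#' @param config a [funnel_config()].
#' @return Filtered [variant_set()].
#' @export
rarity_filter <- function(vs, annotations, config = funnel_config()) {
  freq_cols <- grep("^freq_", names(annotations), value = TRUE)
  idx <- match(vs$variants$key, annotations$key)
  if (length(freq_cols) == 0L)
    return(subset_variants(vs, rep(TRUE, length(idx))))
  fm <- vapply(freq_cols, function(cn)
    as.numeric(annotations[[cn]])[idx], numeric(length(idx)))
  fm <- matrix(fm, nrow = length(idx))
  # unannotated variants and absent frequencies count as rare
  n_common <- rowSums(fm > config$max_pop_freq, na.rm = TRUE)
  subset_variants(vs, n_common == 0L)
}

FUNC_EXONIC <- c("nonsynonymous", "stopgain", "splice",
                 "frameshift_indel", "nonframeshift_indel", "other_exonic")
FUNC_LOF <- c("stopgain", "splice", "frameshift_indel")
FUNC_CLASSES <- c(FUNC_EXONIC, "synonymous", "non_exonic")

#' Functional-class filter
#'
#' Keeps exonic, non-synonymous variant classes (including splice and
#' indel classes); synonymous and non-exonic variants, and variants
#' without an annotation record, are removed.
#'
#' @inheritParams rarity_filter
#' @return Filtered [variant_set()].
#' @export
functional_filter <- function(vs, annotations) {
  idx <- match(vs$variants$key, annotations$key)
  cls <- annotations$func_class[idx]
  subset_variants(vs, !is.na(cls) & cls %in% FUNC_EXONIC)
}

#' Gene-list filters: commonly-mutated exclusion, brain expression
#'
#' Two sequential stages: variants in commonly mutated genes (mucins,
#' olfactory receptors, ...) are excluded, then only variants in genes
#' known to be expressed in brain are retained. A variant without a gene
#' symbol is removed at the brain-expression stage.
#'
#' @inheritParams rarity_filter
#' @param cmd_genes,brain_genes character vectors of gene symbols.
#' @return List with elements `after_cmd` and `after_brain`, both
#'   [variant_set()]s.
#' @export
gene_list_filters <- function(vs, annotations, cmd_genes, brain_genes) {
  idx <- match(vs$variants$key, annotations$key)
  gene <- annotations$gene[idx]
  keep_cmd <- is.na(gene) | !(gene %in% cmd_genes)
  after_cmd <- subset_variants(vs, keep_cmd)
  gene2 <- gene[keep_cmd]
  keep_brain <- !is.na(gene2) & gene2 %in% brain_genes
  list(after_cmd = after_cmd,
       after_brain = subset_variants(after_cmd, keep_brain))
}

#' Pathogenicity and conservation vote
#'
#' A variant passes iff it is a loss-of-function class (stop gain,
#' splice, frameshift indel) or it has at least `min_deleterious`
#' deleterious pathogenicity calls and at least `min_conserved`
#' conserved conservation calls. Missing predictor calls count against
#' the vote.
#'
#' @param annotations annotation table rows to vote on.
#' @param config a [funnel_config()].
#' @return Logical vector, `TRUE` = pass.
#' @export
pathogenicity_vote <- function(annotations, config = funnel_config()) {
  patho_cols <- grep("^patho_", names(annotations), value = TRUE)
  cons_cols <- grep("^cons_", names(annotations), value = TRUE)
  n_del <- rowSums(annotations[, patho_cols, drop = FALSE] == "deleterious",
                   na.rm = TRUE)
  n_cons <- rowSums(annotations[, cons_cols, drop = FALSE] == "conserved",
                    na.rm = TRUE)
  lof <- annotations$func_class %in% FUNC_LOF
  lof | (n_del >= config$min_deleterious & n_cons >= config$min_conserved)
}

#' Candidate-gene prioritization
#'
#' Flags each variant `known_candidate` if its gene is on the
#' neurodegeneration candidate list, else `network_linked` if any direct
#' neighbor in the gene network is, else `neither`.
#'
#' @inheritParams rarity_filter
#' @param nd_genes candidate gene symbols.
#' @param network data frame of undirected edges (`gene1`, `gene2`).
#' @return Character vector of flags, one per variant.
#' @export
candidate_prioritize <- function(vs, annotations, nd_genes, network) {
  idx <- match(vs$variants$key, annotations$key)
  gene <- annotations$gene[idx]
  vapply(gene, function(g) {
    if (is.na(g)) return("neither")
    if (g %in% nd_genes) return("known_candidate")
    nb <- c(network$gene2[network$gene1 == g],
            network$gene1[network$gene2 == g])
    if (any(nb %in% nd_genes)) "network_linked" else "neither"
  }, character(1), USE.NAMES = FALSE)
}

#' Run the full prioritization funnel
#'
#' Applies the ordered stages union -> quality -> shared regions ->
#' dominant segregation -> rarity -> functional class -> commonly-mutated
#' exclusion -> brain expression -> pathogenicity vote, then flags the
#' survivors by candidate-gene status. Stage counts are monotone
#' non-increasing; both survivors and removals are reported.
#'
#' @param call_lists per-individual call lists for [union_variants()],
#'   or an already unified [variant_set()].
#' @param annotations annotation table ([read_annotations()]).
#' @param cmd_genes,brain_genes,nd_genes gene lists.
#' @param network undirected edge data frame.
#' @param config a [funnel_config()]; `case_ids`/`control_ids` drive the
#'   segregation stage and the shared-region scan.
#' @param apply_shared_regions whether to run the IBS shared-region scan
#'   between the first two cases and restrict variants to the detected
#'   regions (skipped with a message when fewer than `window_size`
#'   informative sites are available on every chromosome).
#' @return An object of class `funnel_report`: data frame of stages with
#'   columns `stage`, `n_surviving`, `n_removed`, plus attributes
#'   `survivors` (list of key sets per stage), `final` (the final
#'   [variant_set()]) and `flags` (candidate flags for the final set).
#' @export
run_funnel <- function(call_lists, annotations, cmd_genes, brain_genes,
                       nd_genes, network, config = funnel_config(),
                       apply_shared_regions = TRUE) {
  vs <- if (inherits(call_lists, "variant_set")) call_lists
        else union_variants(call_lists)
  stages <- list(union = vs)
  stages$quality <- quality_filter(stages$union)
  cur <- stages$quality
  if (apply_shared_regions && length(config$case_ids) >= 2L) {
    regions <- shared_regions(cur, config$case_ids[1:2], config)
    if (nrow(regions) > 0L) {
      cur <- subset_variants(cur, region_intersect(cur$variants, regions))
    } else {
      message("no shared regions detected; shared-region stage keeps all")
    }
    stages$shared_regions <- cur
  }
  stages$dominant <- dominant_filter(cur, config$case_ids,
                                     config$control_ids,
                                     config$control_nocall_rescue)
  stages$rare <- rarity_filter(stages$dominant, annotations, config)
  stages$functional <- functional_filter(stages$rare, annotations)
  gl <- gene_list_filters(stages$functional, annotations, cmd_genes,
                          brain_genes)
  stages$cmd_excluded <- gl$after_cmd
  stages$brain_expressed <- gl$after_brain
  idx <- match(stages$brain_expressed$variants$key, annotations$key)
  vote <- rep(FALSE, length(idx))
  vote[!is.na(idx)] <-
    pathogenicity_vote(annotations[idx[!is.na(idx)], , drop = FALSE],
                       config)
  stages$pathogenic <- subset_variants(stages$brain_expressed, vote)
  flags <- candidate_prioritize(stages$pathogenic, annotations, nd_genes,
                                network)
  n <- vapply(stages, length, integer(1))
  report <- data.frame(stage = names(stages), n_surviving = unname(n),
                       n_removed = unname(c(0L, -diff(n))))
  structure(report,
            survivors = lapply(stages, function(s) s$variants$key),
            final = stages$pathogenic, flags = flags,
            class = c("funnel_report", "data.frame"))
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Variant prioritization funnel\n")
  print(as.data.frame(x), row.names = FALSE)
  fin <- attr(x, "final")
  fl <- attr(x, "flags")
  if (length(fl) > 0L) {
    cat("final candidates:\n")
    print(data.frame(key = fin$variants$key, flag = fl),
          row.names = FALSE)
  }
  invisible(x)
}
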