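# Seeded generators emulating the study's inputs: gene-dropped family
# genotypes with a planted fully penetrant dominant variant, annotation
# tables tuned to per-stage retention probabilities, and correlated
# probe-level expression matrices. Every generator is bit-reproducible
# from (seed, config) and returns the ground truth needed by tests.

#' Gene-drop simulation configuration
#'
#' @param n_variants number of background variants.
#' @param freq alt allele frequency of background variants (single value
#'   or vector recycled over sites).
#' @param nocall_rate per-genotype probability of a no-call.
#' @param lowq_rate probability that a called genotype is flagged `low`
#'   instead of `VQHIGH`.
#' @param planted `NULL` or a list with `chrom`, `pos`, `ref`, `alt`:
#'   a variant made heterozygous in every affected member and absent
#'   (homozygous reference) elsewhere, i.e. transmitted fully linked to
#'   the disease.
#' @param linked_chrom `NULL` for unlinked background sites, or a
#'   chromosome name: sites on it are transmitted on founder haplotypes
#'   with `n_crossovers` crossovers per meiosis, so that true IBD
#'   segments exist.
#' @param n_crossovers crossovers per meiosis on the linked chromosome.
#' @return List of class `gene_drop_config`.
#' @export
gene_drop_config <- function(n_variants = 1000L, freq = 0.3,
                             nocall_rate = 0.02, lowq_rate = 0.05,
                             planted = NULL, linked_chrom = NULL,
                             n_crossovers = 1L) {
  stopifnot(n_variants >= 0, all(freq > 0), all(freq < 1),
            nocall_rate >= 0, nocall_rate <= 1,
            lowq_rate >= 0, lowq_rate <= 1, n_crossovers >= 0)
  structure(list(n_variants = as.integer(n_variants), freq = freq,
                 nocall_rate = nocall_rate, lowq_rate = lowq_rate,
                 planted = planted, linked_chrom = linked_chrom,
                 n_crossovers = as.integer(n_crossovers)),
            class = "gene_drop_config")
}

#' Gene-drop genotypes through a pedigree
#'
#' Draws founder haplotypes from the configured allele-frequency
#' spectrum and transmits them through the pedigree. Unlinked sites
#' segregate independently; on a linked chromosome each meiosis
#' transmits a single recombination-free mosaic with `n_crossovers`
#' uniform crossovers, and the founder-haplotype labels of every
#' transmission are recorded so true IBD segments are known. The planted
#' variant is heterozygous in every affected member and homozygous
#' reference elsewhere (full penetrance, complete linkage). No-call and
#' low-quality flags are injected at the configured rates (the planted
#' variant is exempt from no-calls so that segregation is preserved by
#' construction).
#'
#' @param ped a [pedigree()].
#' @param config a [gene_drop_config()].
#' @param seed integer seed.
#' @return List with `vs` (a [variant_set()] over all pedigree members)
#'   and `truth`: founder haplotype labels per individual and site
#'   (`hap_labels`), per-pair true IBD indicator function, planted
#'   carrier ids, per-site allele frequencies.
#' @export
gene_drop <- function(ped, config = gene_drop_config(), seed = 1) {
  set.seed(derive_seed(seed, "gene_drop"))
  n <- config$n_variants
  ids <- ped$id
  freq <- rep_len(config$freq, n)
  fndr <- founders(ped)
  # founder haplotype labels: founder j carries labels 2j-1, 2j
  lab <- setNames(lapply(seq_along(fndr), function(j) c(2L*j-1L, 2L*j)),
                  fndr)
  # founder haplotype alleles per site: label -> 0/1 vector
  hap_allele <- matrix(0L, nrow = 2L * length(fndr), ncol = n)
  for (h in seq_len(nrow(hap_allele)))
    hap_allele[h, ] <- rbinom(n, 1L, freq)

  linked <- !is.null(config$linked_chrom)
  # per-individual per-site haplotype label matrices (2 slots)
  slot1 <- matrix(0L, length(ids), n, dimnames = list(ids, NULL))
  slot2 <- matrix(0L, length(ids), n, dimnames = list(ids, NULL))
  for (f in fndr) {
    slot1[f, ] <- lab[[f]][1]
    slot2[f, ] <- lab[[f]][2]
  }
  meiosis_mosaic <- function() {
    # origin slot per site for one gamete
    if (!linked) return(sample.int(2L, n, replace = TRUE))
    o <- integer(n)
    cur <- sample.int(2L, 1L)
    bp <- sort(sample.int(n, min(config$n_crossovers, n)))
    j <- 1L
    for (i in seq_len(n)) {
      while (j <= length(bp) && i > bp[j]) { cur <- 3L - cur; j <- j + 1L }
      o[i] <- cur
    }
    o
  }
  remaining <- setdiff(ids, fndr)
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(id) {
      i <- match(id, ids)
      !(ped$father[i] %in% remaining) && !(ped$mother[i] %in% remaining)
    }, logical(1))]
    if (length(ready) == 0L) stop_input("pedigree not orderable")
    for (id in ready) {
      i <- match(id, ids)
      fo <- meiosis_mosaic(); mo <- meiosis_mosaic()
      fa <- ped$father[i]; mo_id <- ped$mother[i]
      slot1[id, ] <- ifelse(fo == 1L, slot1[fa, ], slot2[fa, ])
      slot2[id, ] <- ifelse(mo == 1L, slot1[mo_id, ], slot2[mo_id, ])
    }
    remaining <- setdiff(remaining, ready)
  }
  a1 <- matrix(hap_allele[cbind(c(slot1), rep(seq_len(n), each = length(ids)))],
               length(ids), n, dimnames = list(ids, NULL))
  a2 <- matrix(hap_allele[cbind(c(slot2), rep(seq_len(n), each = length(ids)))],
               length(ids), n, dimnames = list(ids, NULL))

  chrom <- rep(config$linked_chrom %||% "1", n)
  pos <- seq_len(n) * 1000L
  variants <- data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", n), alt = rep("G", n))
  gt <- matrix(paste0(t(a1), "/", t(a2)), n, length(ids),
               dimnames = list(NULL, ids))
  qual <- matrix(ifelse(runif(n * length(ids)) < config$lowq_rate,
                        "low", "VQHIGH"),
                 n, length(ids), dimnames = list(NULL, ids))
  nc <- matrix(runif(n * length(ids)) < config$nocall_rate,
               n, length(ids))
  gt[nc] <- GT_NOCALL
  qual[nc] <- "nocall"

  planted_carriers <- character()
  if (!is.null(config$planted)) {
    p <- config$planted
    planted_carriers <- ped$id[ped$affection == "affected"]
    pg <- ifelse(ids %in% planted_carriers, "0/1", "0/0")
    variants <- rbind(variants,
                      data.frame(chrom = p$chrom, pos = as.integer(p$pos),
                                 ref = p$ref, alt = p$alt))
    gt <- rbind(gt, matrix(pg, 1, dimnames = list(NULL, ids)))
    qual <- rbind(qual, matrix("VQHIGH", 1, length(ids),
                               dimnames = list(NULL, ids)))
  }
  ord <- order(variants$chrom, variants$pos)
  vs <- variant_set(variants[ord, , drop = FALSE],
                    gt[ord, , drop = FALSE], qual[ord, , drop = FALSE])
  ibd_sites <- function(id_a, id_b) {
    # TRUE where the pair shares at least one founder haplotype label
    slot1[id_a, ] == slot1[id_b, ] | slot1[id_a, ] == slot2[id_b, ] |
      slot2[id_a, ] == slot1[id_b, ] | slot2[id_a, ] == slot2[id_b, ]
  }
  list(vs = vs,
       truth = list(slot1 = slot1, slot2 = slot2, pos = pos,
                    chrom = config$linked_chrom %||% "1",
                    hap_allele = hap_allele, freq = freq,
                    ibd_sites = ibd_sites,
                    planted_carriers = planted_carriers,
                    planted_key = if (is.null(config$planted)) NULL
                    else with(config$planted,
                              variant_key(chrom, pos, ref, alt))))
}

#' Synthetic annotation tables tuned to funnel retention
#'
#' Annotates a call set so that the planted variant satisfies every
#' funnel rule (rare, nonsynonymous, non-commonly-mutated gene,
#' brain-expressed, 7 of 8 predictors deleterious, 3 of 4 scores
#' conserved, candidate gene) while each background variant passes each
#' late funnel stage independently with the configured probability.
#'
#' @param vs a [variant_set()].
#' @param truth the `truth` component of [gene_drop()] (used for the
#'   planted key; may be `NULL`).
#' @param retention named numeric vector of per-stage pass
#'   probabilities: `rare`, `functional`, `cmd`, `brain`, `patho`,
#'   `candidate` (probability that a surviving gene is ND-linked).
#' @param planted_gene gene symbol for the planted variant.
#' @param seed integer seed.
#' @return List: `annotations` data frame (one row per variant),
#'   `cmd_genes`, `brain_genes`, `nd_genes`, `network` (edge data
#'   frame).
#' @export
make_annotations <- function(vs, truth = NULL,
                             retention = c(rare = 0.5, functional = 0.5,
                                           cmd = 0.9, brain = 0.6,
                                           patho = 0.3, candidate = 0.1),
                             planted_gene = "ADAM17", seed = 1) {
  set.seed(derive_seed(seed, "make_annotations"))
  keys <- vs$variants$key
  n <- length(keys)
  planted_key <- truth$planted_key %||% ""
  is_planted <- keys == planted_key
  gene <- sprintf("GENE%05d", seq_len(n))
  gene[is_planted] <- planted_gene

  pass_rare <- runif(n) < retention[["rare"]]
  pass_func <- runif(n) < retention[["functional"]]
  pass_cmd <- runif(n) < retention[["cmd"]]
  pass_brain <- runif(n) < retention[["brain"]]
  pass_patho <- runif(n) < retention[["patho"]]
  is_candidate <- runif(n) < retention[["candidate"]]
  pass_rare[is_planted] <- TRUE; pass_func[is_planted] <- TRUE
  pass_cmd[is_planted] <- TRUE; pass_brain[is_planted] <- TRUE
  pass_patho[is_planted] <- TRUE; is_candidate[is_planted] <- TRUE

  freq_esp <- ifelse(pass_rare, runif(n, 0, 0.01), runif(n, 0.02, 0.5))
  freq_exac <- ifelse(pass_rare, runif(n, 0, 0.01), runif(n, 0.02, 0.5))
  freq_esp[is_planted] <- 0.000077
  freq_exac[is_planted] <- 0.0001049
  func_class <- ifelse(pass_func, "nonsynonymous",
                       sample(c("synonymous", "non_exonic"), n,
                              replace = TRUE))
  predictors <- c("SIFT", "Polyphen2_HDIV", "Polyphen2_HVAR", "LRT",
                  "MutationTaster", "PROVEAN", "MetaSVM", "FATHMM-MKL")
  cons_scores <- c("DAMN", "CADD", "GERP", "SiPHY")
  patho <- matrix("tolerated", n, length(predictors),
                  dimnames = list(NULL, paste0("patho_", predictors)))
  cons <- matrix("not_conserved", n, length(cons_scores),
                 dimnames = list(NULL, paste0("cons_", cons_scores)))
  for (i in seq_len(n)) {
    nd <- if (pass_patho[i]) sample(5:8, 1L) else sample(0:4, 1L)
    nc <- if (pass_patho[i]) sample(2:4, 1L) else sample(0:1, 1L)
    if (is_planted[i]) { nd <- 7L; nc <- 3L }
    patho[i, sample(length(predictors), nd)] <- "deleterious"
    cons[i, sample(length(cons_scores), nc)] <- "conserved"
  }
  cmd_genes <- c(gene[!pass_cmd & !is_planted], "MUC16", "OR2T35")
  brain_genes <- c(gene[pass_brain], "APP")
  nd_genes <- c("ADAM17", "ADRA2A", "APP")
  linked <- !is_planted & is_candidate
  network <- data.frame(
    gene1 = c(gene[linked], planted_gene),
    gene2 = c(sample(nd_genes, sum(linked), replace = TRUE), "APP"))
  ann <- data.frame(chrom = vs$variants$chrom, pos = vs$variants$pos,
                    ref = vs$variants$ref, alt = vs$variants$alt,
                    key = keys, gene = gene, func_class = func_class,
                    freq_ESP6500_ea = freq_esp,
                    freq_ExAC_NFE = freq_exac,
                    stringsAsFactors = FALSE)
  ann <- cbind(ann, as.data.frame(patho, stringsAsFactors = FALSE),
               as.data.frame(cons, stringsAsFactors = FALSE))
  # genes on the candidate list itself always count as known candidates
  list(annotations = ann, cmd_genes = unique(cmd_genes),
       brain_genes = unique(brain_genes), nd_genes = nd_genes,
       network = unique(network))
}

#' Synthetic correlated expression matrices
#'
#' Latent per-sample gene values are drawn so that each target gene has
#' the configured population Pearson correlation with the anchor gene
#' (`target = r * anchor + sqrt(1 - r^2) * noise`, all standard normal,
#' then shifted/scaled to a microarray-like log2 scale). Probes add
#' independent Gaussian noise to their gene's latent value. Detection
#' p-values are drawn Uniform(0, 0.04) for called cells and
#' Uniform(0.05, 1) for no-call cells, keeping the 0.05 threshold exact.
#'
#' @param anchor anchor gene symbol.
#' @param targets data frame with columns `gene` and `r` (true
#'   correlation with the anchor, each in (-1, 1)).
#' @param n_ad,n_control samples per group.
#' @param probes_per_gene probes simulated per gene.
#' @param noise_sd probe-level noise standard deviation.
#' @param call_rate probability a cell is called.
#' @param mean_log2,sd_log2 location/scale of the latent log2 signal.
#' @param seed integer seed.
#' @return An [expression_set()] (`log2_transformed = TRUE`) with
#'   attribute `truth` (the latent gene values).
#' @export
make_expression <- function(anchor = "ADAM17",
                            targets = data.frame(gene = "APP",
                                                 r = -sqrt(0.55)),
                            n_ad = 201L, n_control = 83L,
                            probes_per_gene = 2L, noise_sd = 0.25,
                            call_rate = 0.98, mean_log2 = 8, sd_log2 = 1,
                            seed = 1) {
  stopifnot(all(abs(targets$r) < 1), n_ad + n_control >= 3)
  set.seed(derive_seed(seed, "make_expression"))
  n <- n_ad + n_control
  samples <- sprintf("S%03d", seq_len(n))
  groups <- setNames(rep(c("AD", "control"), c(n_ad, n_control)),
                     samples)
  za <- rnorm(n)
  latent <- list()
  latent[[anchor]] <- za
  for (i in seq_len(nrow(targets))) {
    r <- targets$r[i]
    latent[[targets$gene[i]]] <- r * za + sqrt(1 - r^2) * rnorm(n)
  }
  genes <- names(latent)
  probe_rows <- list()
  probe_map <- list()
  for (g in genes) {
    vals <- mean_log2 + sd_log2 * latent[[g]]
    for (j in seq_len(probes_per_gene)) {
      pr <- sprintf("ILMN_%s_%02d", g, j)
      probe_rows[[pr]] <- vals + rnorm(n, 0, noise_sd)
      probe_map[[pr]] <- data.frame(probe = pr, gene = g)
    }
  }
  intens <- do.call(rbind, probe_rows)
  colnames(intens) <- samples
  called <- matrix(runif(length(intens)) < call_rate, nrow(intens))
  detp <- matrix(0, nrow(intens), ncol(intens),
                 dimnames = dimnames(intens))
  detp[called] <- runif(sum(called), 0, 0.04)
  detp[!called] <- runif(sum(!called), 0.05, 1)
  es <- expression_set(intens, detp, groups,
                       do.call(rbind, probe_map), log2_transformed = TRUE)
  attr(es, "truth") <- latent
  es
}
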