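test_that("union_variants merges by key and fills no-calls", {
  a <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G",
                  gt = c("0/1", "0/1"), qual = c("VQHIGH", "VQHIGH"))
  b <- data.frame(chrom = "1", pos = c(100L, 300L), ref = "A", alt = "G",
                  gt = c("1/1", "0/1"), qual = c("VQHIGH", "low"))
  vs <- union_variants(list(I1 = a, I2 = b))
  expect_identical(length(vs), 3L)
  expect_identical(unname(vs$gt[vs$variants$pos == 200L, "I2"]), "./.")
  expect_identical(unname(vs$qual[vs$variants$pos == 200L, "I2"]), "nocall")
  expect_identical(unname(vs$gt[vs$variants$pos == 100L, "I2"]), "1/1")
})

test_that("same site with different ALT alleles yields two records", {
  a <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                  gt = "0/1", qual = "VQHIGH")
  b <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "T",
                  gt = "0/1", qual = "VQHIGH")
  vs <- union_variants(list(I1 = a, I2 = b))
  expect_identical(length(vs), 2L)
  expect_setequal(vs$variants$alt, c("G", "T"))
})

test_that("conflicting REF at one position is an input error; empty input is empty", {
  a <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                  gt = "0/1", qual = "VQHIGH")
  b <- data.frame(chrom = "1", pos = 100L, ref = "C", alt = "G",
                  gt = "0/1", qual = "VQHIGH")
  expect_error(union_variants(list(I1 = a, I2 = b)), "REF")
  empty <- union_variants(list(I1 = a[0, ], I2 = b[0, ]))
  expect_identical(length(empty), 0L)
})

test_that("quality_filter keeps any-VQHIGH variants and recounts removals", {
  ids <- c("A", "B", "C")
  vs <- make_vs(list(c("0/1", "0/0", "0/0"),
                     c("0/1", "0/1", "0/1"),
                     c("./.", "0/1", "0/0")), ids,
                qual_rows = list(c("VQHIGH", "low", "low"),
                                 c("low", "low", "low"),
                                 c("nocall", "low", "low")))
  out <- quality_filter(vs)
  expect_identical(length(out), 1L)
  expect_identical(attr(out, "removed"), 2L)

  set.seed(4)
  n <- 1000
  qual <- matrix(sample(c("VQHIGH", "low"), n * 3, TRUE, c(0.3, 0.7)),
                 n, 3, dimnames = list(NULL, ids))
  gt <- matrix("0/1", n, 3, dimnames = list(NULL, ids))
  vs2 <- variant_set(data.frame(chrom = "1", pos = seq_len(n),
                                ref = "A", alt = "G"), gt, qual)
  expect_identical(length(quality_filter(vs2)),
                   sum(rowSums(qual == "VQHIGH") > 0))
})

test_that("dominant_filter equals exhaustive rule enumeration", {
  ids <- c("case1", "case2", "ctrl1", "ctrl2")
  states <- c("0/0", "0/1", "1/1", "./.")
  combos <- expand.grid(states, states, states, states,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i)
    unlist(combos[i, ], use.names = FALSE))
  vs <- make_vs(rows, ids, pos = seq_len(nrow(combos)))
  out <- dominant_filter(vs, c("case1", "case2"), c("ctrl1", "ctrl2"))
  # independent restatement of the rule
  expected <- vapply(seq_len(nrow(combos)), function(i) {
    cs <- unlist(combos[i, 1:2]); ct <- unlist(combos[i, 3:4])
    all(cs %in% c("0/1", "./.")) && any(cs == "0/1") &&
      all(ct == "0/0")
  }, logical(1))
  expect_setequal(out$variants$pos, which(expected))
  # canonical segregating pattern: het cases, hom-ref controls -> kept
  expect_true(variant_key("1", which(combos[, 1] == "0/1" &
                                       combos[, 2] == "0/1" &
                                       combos[, 3] == "0/0" &
                                       combos[, 4] == "0/0")[1],
                          "A", "G") %in% out$variants$key)
  expect_error(dominant_filter(vs, c("case1"), c("case1")), "both")
  # laxer reading rescues control no-calls
  out2 <- dominant_filter(vs, c("case1", "case2"), c("ctrl1", "ctrl2"),
                          control_nocall_rescue = TRUE)
  expect_gt(length(out2), length(out))
})

test_that("rarity_filter keeps the 1% boundary and unannotated variants", {
  ids <- "A"
  vs <- make_vs(list("0/1", "0/1", "0/1", "0/1"), ids)
  ann <- data.frame(key = vs$variants$key[1:3],
                    gene = "G1", func_class = "nonsynonymous",
                    freq_ESP6500_ea = c(0.000077, 0.05, 0.01),
                    freq_ExAC_NFE = c(0.0001049, NA, NA))
  out <- rarity_filter(vs, ann, funnel_config())
  # rare, removed (5%), boundary exactly 1% kept, unannotated kept
  expect_setequal(out$variants$pos, c(100L, 300L, 400L))
})

test_that("functional_filter matches the class rule table", {
  classes <- c("nonsynonymous", "synonymous", "stopgain", "splice",
               "frameshift_indel", "nonframeshift_indel", "other_exonic",
               "non_exonic")
  vs <- make_vs(as.list(rep("0/1", 8)), "A", pos = 1:8)
  ann <- data.frame(key = vs$variants$key, gene = "G",
                    func_class = classes)
  out <- functional_filter(vs, ann)
  keep_expected <- !classes %in% c("synonymous", "non_exonic")
  expect_setequal(out$variants$pos, which(keep_expected))
  # a variant with no annotation row is removed
  out2 <- functional_filter(vs, ann[-1, ])
  expect_false(1L %in% out2$variants$pos)
})

test_that("gene-list filters match direct set arithmetic on a random fixture", {
  set.seed(7)
  n <- 500
  vs <- make_vs(as.list(rep("0/1", n)), "A", pos = seq_len(n))
  genes <- sprintf("G%03d", sample.int(200, n, TRUE))
  ann <- data.frame(key = vs$variants$key, gene = genes,
                    func_class = "nonsynonymous")
  cmd <- sprintf("G%03d", sample.int(200, 30))
  brain <- sprintf("G%03d", sample.int(200, 120))
  out <- gene_list_filters(vs, ann, cmd, brain)
  expect_identical(length(out$after_cmd), sum(!genes %in% cmd))
  expect_identical(length(out$after_brain),
                   sum(!genes %in% cmd & genes %in% brain))
})

test_that("pathogenicity_vote thresholds and LoF override match the rule", {
  mk_ann <- function(n_del, n_cons, cls = "nonsynonymous") {
    patho <- setNames(as.list(rep("tolerated", 8)),
                      paste0("patho_P", 1:8))
    patho[seq_len(n_del)] <- "deleterious"
    cons <- setNames(as.list(rep("not_conserved", 4)),
                     paste0("cons_C", 1:4))
    cons[seq_len(n_cons)] <- "conserved"
    as.data.frame(c(list(key = "k", gene = "G", func_class = cls),
                    patho, cons))
  }
  cfg <- funnel_config()
  # full boundary enumeration against the written rule
  for (nd in 0:8) for (nc in 0:4) {
    expect_identical(pathogenicity_vote(mk_ann(nd, nc), cfg),
                     nd >= 5 && nc >= 2, info = paste(nd, nc))
  }
  expect_true(pathogenicity_vote(mk_ann(7, 3), cfg))    # 7/8 and 3/4
  expect_false(pathogenicity_vote(mk_ann(0, 4), cfg))
  expect_true(pathogenicity_vote(mk_ann(0, 0, "stopgain"), cfg))
  expect_true(pathogenicity_vote(mk_ann(0, 0, "frameshift_indel"), cfg))
  # missing calls count against the vote
  ann <- mk_ann(5, 2); ann$patho_P1 <- NA
  expect_false(pathogenicity_vote(ann, cfg))
})

test_that("candidate_prioritize matches a brute-force neighborhood scan", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:40)
  edges <- data.frame(gene1 = sample(genes, 60, TRUE),
                      gene2 = sample(genes, 60, TRUE))
  nd <- sample(genes, 6)
  vs <- make_vs(as.list(rep("0/1", 40)), "A", pos = 1:40)
  ann <- data.frame(key = vs$variants$key, gene = genes,
                    func_class = "nonsynonymous")
  flags <- candidate_prioritize(vs, ann, nd, edges)
  for (i in seq_along(genes)) {
    g <- genes[i]
    nbrs <- unique(c(edges$gene2[edges$gene1 == g],
                     edges$gene1[edges$gene2 == g]))
    want <- if (g %in% nd) "known_candidate"
            else if (any(nbrs %in% nd)) "network_linked" else "neither"
    expect_identical(flags[i], want)
  }
})

test_that("run_funnel keeps a planted qualifying variant and is monotone", {
  ped <- ad_family("wgs")
  gd <- gene_drop(ped, gene_drop_config(
    n_variants = 300, planted = list(chrom = "2", pos = 9628047L,
                                     ref = "G", alt = "T")), seed = 21)
  ann <- make_annotations(gd$vs, gd$truth, seed = 21)
  cfg <- funnel_config(case_ids = c("200", "102"),
                       control_ids = c("122", "123"))
  rep <- run_funnel(gd$vs, ann$annotations, ann$cmd_genes,
                    ann$brain_genes, ann$nd_genes, ann$network, cfg,
                    apply_shared_regions = FALSE)
  expect_true(all(diff(rep$n_surviving) <= 0))
  expect_identical(rep$n_surviving[1],
                   rep$n_surviving[nrow(rep)] +
                     sum(rep$n_removed))
  fin <- attr(rep, "final")
  expect_true(gd$truth$planted_key %in% fin$variants$key)
  expect_identical(attr(rep, "flags")[match(gd$truth$planted_key,
                                            fin$variants$key)],
                   "known_candidate")
})

test_that("funnel result is invariant to variant input order", {
  ped <- ad_family("wgs")
  gd <- gene_drop(ped, gene_drop_config(
    n_variants = 100, planted = list(chrom = "2", pos = 9628047L,
                                     ref = "G", alt = "T")), seed = 3)
  ann <- make_annotations(gd$vs, gd$truth, seed = 3)
  cfg <- funnel_config(case_ids = c("200", "102"),
                       control_ids = c("122", "123"))
  run1 <- run_funnel(gd$vs, ann$annotations, ann$cmd_genes,
                     ann$brain_genes, ann$nd_genes, ann$network, cfg,
                     apply_shared_regions = FALSE)
  perm <- sample(length(gd$vs))
  vs2 <- variant_set(gd$vs$variants[perm, c("chrom", "pos", "ref", "alt")],
                     gd$vs$gt[perm, , drop = FALSE],
                     gd$vs$qual[perm, , drop = FALSE])
  run2 <- run_funnel(vs2, ann$annotations, ann$cmd_genes,
                     ann$brain_genes, ann$nd_genes, ann$network, cfg,
                     apply_shared_regions = FALSE)
  expect_identical(run1$n_surviving, run2$n_surviving)
  expect_setequal(attr(run1, "final")$variants$key,
                  attr(run2, "final")$variants$key)
})

test_that("empty variant input gives an all-zero report", {
  empty_calls <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), gt = character(), qual = character())
  empty <- union_variants(list(I1 = empty_calls, I2 = empty_calls))
  ann <- data.frame(key = character(), gene = character(),
                    func_class = character())
  rep <- run_funnel(empty, ann, character(), character(), character(),
                    data.frame(gene1 = character(), gene2 = character()),
                    funnel_config(case_ids = "I1", control_ids = "I2"),
                    apply_shared_regions = FALSE)
  expect_true(all(rep$n_surviving == 0L))
})
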