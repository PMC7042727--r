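# Readers and writers for the minimal formats the pipeline exchanges:
# a VCF 4.2 subset (CHROM, POS, REF, ALT, FORMAT GT:VQ), annotation
# tables, gene lists, network edge lists, expression matrices and the
# JSON run configuration. All writers are deterministic (stable
# ordering, fixed float formatting).

#' Read the supported VCF subset
#'
#' Parses a plain-text VCF 4.2 file restricted to the fields the
#' pipeline uses: CHROM, POS (1-based), REF, ALT and per-sample
#' `GT:VQ`, where `VQ` is the genotype quality flag (`VQHIGH`, `low`,
#' `nocall`). A sample lacking GT at a site (or `.`) receives a
#' no-call. Malformed records raise errors naming the line.
#'
#' @param path file path.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L)
    stop_input("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop_input("VCF must carry FORMAT and at least one sample: ", path)
  samples <- cols[-(1:9)]
  body <- which(!startsWith(lines, "#"))
  body <- body[body > hdr & nzchar(lines[body])]
  n <- length(body)
  gt <- matrix(GT_NOCALL, n, length(samples),
               dimnames = list(NULL, samples))
  qual <- matrix("nocall", n, length(samples),
                 dimnames = list(NULL, samples))
  chrom <- character(n); pos <- integer(n)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols))
      stop_input("line ", ln, ": expected ", length(cols), " fields")
    chrom[i] <- f[1]
    pos[i] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[i])) stop_input("line ", ln, ": bad POS '", f[2], "'")
    ref[i] <- f[4]; alt[i] <- f[5]
    if (grepl(",", alt[i], fixed = TRUE))
      stop_input("line ", ln, ": multiallelic ALT not supported")
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt); qi <- match("VQ", fmt)
    for (s in seq_along(samples)) {
      sub <- strsplit(f[9 + s], ":", fixed = TRUE)[[1]]
      g <- if (!is.na(gi) && gi <= length(sub)) sub[gi] else "./."
      if (g %in% c(".", "")) g <- GT_NOCALL
      g <- gsub("|", "/", g, fixed = TRUE)
      if (!grepl("^[01.]/[01.]$", g))
        stop_input("line ", ln, ": malformed GT '", g, "'")
      q <- if (!is.na(qi) && qi <= length(sub)) sub[qi] else NA
      if (is.na(q) || !q %in% c("VQHIGH", "low", "nocall"))
        q <- if (gt_is_nocall(g)) "nocall" else "low"
      if (gt_is_nocall(g)) q <- "nocall"
      if (q == "nocall" && !gt_is_nocall(g)) q <- "low"
      gt[i, s] <- g; qual[i, s] <- q
    }
  }
  dup <- duplicated(data.frame(chrom, pos))
  refs <- data.frame(chrom, pos, ref)
  if (nrow(unique(refs)) != nrow(unique(refs[, 1:2])))
    stop_input("conflicting REF alleles at a shared position in ", path)
  variant_set(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt),
              gt, qual)
}

#' @rdname read_vcf
#' @param vs a [variant_set()] to write.
#' @export
write_vcf <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=VQ,Number=1,Type=String,",
           "Description=\"Genotype quality flag\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", vs$individuals), collapse = "\t")), con)
  ord <- order(vs$variants$chrom, vs$variants$pos, vs$variants$alt)
  for (i in ord) {
    cells <- paste(vs$gt[i, ], vs$qual[i, ], sep = ":")
    writeLines(paste(c(vs$variants$chrom[i], vs$variants$pos[i], ".",
                       vs$variants$ref[i], vs$variants$alt[i], ".",
                       "PASS", ".", "GT:VQ", cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read an annotation table
#'
#' Tab-separated with mandatory columns `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `func_class`; population frequencies in `freq_*` columns
#' (empty = absent), pathogenicity calls in `patho_*` columns
#' (`deleterious` / `tolerated` / empty) and conservation calls in
#' `cons_*` columns (`conserved` / `not_conserved` / empty). Unknown
#' predictor columns are preserved as additional opaque calls.
#'
#' @param path file path.
#' @return Data frame with an added `key` column.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "func_class")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L)
    stop_input("annotation table lacks column(s): ",
               paste(miss, collapse = ", "))
  bad <- setdiff(unique(ann$func_class), FUNC_CLASSES)
  if (length(bad) > 0L)
    stop_input("unknown func_class value(s): ", paste(bad, collapse = ", "))
  fr <- grep("^freq_", names(ann), value = TRUE)
  for (cn in fr) {
    ann[[cn]] <- suppressWarnings(as.numeric(ann[[cn]]))
    if (any(ann[[cn]] < 0 | ann[[cn]] > 1, na.rm = TRUE))
      stop_input("population frequencies must lie in [0, 1]")
  }
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

#' Read a one-symbol-per-line gene list
#'
#' @param path file path.
#' @return Character vector of unique symbols; empty file gives an
#'   empty set with a warning.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L) warning("empty gene list: ", path)
  x
}

#' Read an undirected gene-network edge list
#'
#' Two-column tab-separated file; duplicated edges (in either
#' orientation) are removed.
#'
#' @param path file path.
#' @return Data frame with columns `gene1`, `gene2`.
#' @export
read_network <- function(path) {
  e <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(e) < 2L) stop_input("network file needs two columns")
  names(e)[1:2] <- c("gene1", "gene2")
  a <- pmin(e$gene1, e$gene2); b <- pmax(e$gene1, e$gene2)
  keep <- !duplicated(paste(a, b))
  e[keep, c("gene1", "gene2"), drop = FALSE]
}

#' Read an expression data set from TSV files
#'
#' @param matrix_path probes x samples intensity TSV (first column =
#'   probe id).
#' @param detp_path matching detection p-value TSV.
#' @param samples_path sample sheet TSV with columns `id`, `group`.
#' @param probemap_path probe map TSV with columns `probe`, `gene`.
#' @param log2_transformed whether intensities are already log2.
#' @return An [expression_set()].
#' @export
read_expression_set <- function(matrix_path, detp_path, samples_path,
                                probemap_path, log2_transformed = FALSE) {
  rd <- function(p) {
    d <- utils::read.delim(p, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  intens <- rd(matrix_path)
  detp <- rd(detp_path)
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(ss)))
    stop_input("sample sheet needs columns id, group")
  pm <- utils::read.delim(probemap_path, stringsAsFactors = FALSE)
  expression_set(intens, detp, setNames(ss$group, ss$id), pm,
                 log2_transformed = log2_transformed)
}

#' Write a funnel report as TSV
#'
#' @param report a `funnel_report` from [run_funnel()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_funnel_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' A single structured file drives a full [run_all()] run. Mandatory
#' keys: `seed`; optional blocks: `paths` (vcf, ped, annotations,
#' cmd_genes, brain_genes, nd_genes, network, expression inputs),
#' `funnel` (overrides for [funnel_config()]), `disease_model`
#' (`freq`, `penetrances`), `theta_grid`, `typed_ids`,
#' `expression` (`alpha`, `min_rate`, `anchor`, `targets`). Unknown
#' keys are rejected; referenced paths must exist.
#'
#' @param path JSON file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "paths", "funnel", "disease_model", "theta_grid",
             "typed_ids", "expression", "simulate", "n_markers")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L)
    stop_input("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop_input("config must set a seed")
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p))
      stop_input("configured path does not exist: ", p)
  }
  structure(cfg, class = c("run_config", class(cfg)))
}
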