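#' Construct a pedigree
#'
#' A pedigree is an ordered collection of individuals with parent links,
#' sex, affection status and a genotype-availability flag. Founders have
#' both parent fields missing (`NA`); every non-founder must have both
#' parents present in the pedigree.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother character vectors of parent ids; `NA` (or `"0"`)
#'   for missing.
#' @param sex `"male"`, `"female"` or `"unknown"` (recycled if length 1).
#' @param affection `"affected"`, `"unaffected"` or `"unknown"`.
#' @param genotyped logical; whether genotype data is available.
#' @param name pedigree (family) name.
#' @param validate if `TRUE` (default), stop on any invariant violation;
#'   see [validate_pedigree()].
#' @return An object of class `pedigree`: a data frame with one row per
#'   individual and attribute `name`.
#' @seealso [read_ped()], [validate_pedigree()], [ad_family()]
#' @export
pedigree <- function(id, father = NA, mother = NA,
                     sex = "unknown", affection = "unknown",
                     genotyped = FALSE, name = "FAM", validate = TRUE) {
  n <- length(id)
  norm_parent <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & p %in% c("0", "")] <- NA_character_
    p
  }
  check_levels <- function(x, levels, what) {
    x <- as.character(x)
    if (!all(x %in% levels))
      stop_input(what, " must be one of ",
                 paste(levels, collapse = "/"))
    x
  }
  ped <- data.frame(
    id = as.character(id),
    father = norm_parent(rep_len(father, n)),
    mother = norm_parent(rep_len(mother, n)),
    sex = check_levels(rep_len(sex, n),
                       c("male", "female", "unknown"), "sex"),
    affection = check_levels(rep_len(affection, n),
                             c("affected", "unaffected", "unknown"),
                             "affection"),
    genotyped = rep_len(as.logical(genotyped), n),
    stringsAsFactors = FALSE
  )
  attr(ped, "name") <- name
  class(ped) <- c("pedigree", "data.frame")
  if (validate) {
    v <- validate_pedigree(ped)
    if (nrow(v) > 0L)
      stop_input("invalid pedigree: ", paste(v$message, collapse = "; "))
  }
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d individuals (%d affected, %d genotyped, %d founders)\n",
              attr(x, "name") %||% "?", nrow(x),
              sum(x$affection == "affected"), sum(x$genotyped),
              sum(is.na(x$father) & is.na(x$mother))))
  print(as.data.frame(x), ...)
  invisible(x)
}

founders <- function(ped) ped$id[is.na(ped$father) & is.na(ped$mother)]

#' Validate pedigree invariants
#'
#' Checks id uniqueness, parental references, parent sex consistency,
#' both-or-neither parent links, acyclicity of the parent-child graph and
#' the presence of at least one founder. Violations are returned as data,
#' not raised as errors.
#'
#' @param ped a [pedigree()].
#' @return A data frame with columns `id`, `rule`, `message`; zero rows
#'   iff all invariants hold.
#' @export
validate_pedigree <- function(ped) {
  bad <- list()
  add <- function(id, rule, message)
    bad[[length(bad) + 1L]] <<- data.frame(id = id, rule = rule,
                                           message = message)
  dup <- unique(ped$id[duplicated(ped$id)])
  for (d in dup) add(d, "unique_id", sprintf("duplicated id '%s'", d))

  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    fa <- ped$father[i]; mo <- ped$mother[i]
    if (is.na(fa) != is.na(mo))
      add(id, "missing_parent",
          sprintf("individual '%s' has exactly one parent recorded", id))
    for (p in c(father = fa, mother = mo)) {
      if (!is.na(p) && !p %in% ped$id)
        add(id, "unknown_parent",
            sprintf("parent '%s' of '%s' is not in the pedigree", p, id))
    }
    if (!is.na(fa) && fa %in% ped$id &&
        ped$sex[match(fa, ped$id)] == "female")
      add(id, "parent_sex", sprintf("father '%s' of '%s' is female", fa, id))
    if (!is.na(mo) && mo %in% ped$id &&
        ped$sex[match(mo, ped$id)] == "male")
      add(id, "parent_sex", sprintf("mother '%s' of '%s' is male", mo, id))
  }

  # cycle detection on the parent -> child relation (DFS with colors)
  kids <- split(ped$id, factor(ped$father, levels = ped$id))
  kids2 <- split(ped$id, factor(ped$mother, levels = ped$id))
  children_of <- function(id) c(kids[[id]], kids2[[id]])
  color <- setNames(rep(0L, nrow(ped)), ped$id)
  cycle_ids <- character()
  visit <- function(id) {
    color[id] <<- 1L
    for (c in children_of(id)) {
      if (!c %in% names(color)) next
      if (color[c] == 1L) cycle_ids <<- union(cycle_ids, c)
      else if (color[c] == 0L) visit(c)
    }
    color[id] <<- 2L
  }
  for (id in ped$id) if (color[id] == 0L) visit(id)
  for (c in cycle_ids)
    add(c, "cycle", sprintf("individual '%s' lies on an ancestry cycle", c))

  if (nrow(ped) > 0L && length(founders(ped)) == 0L)
    add(NA_character_, "no_founder", "pedigree has no founder")

  if (length(bad) == 0L)
    return(data.frame(id = character(), rule = character(),
                      message = character()))
  do.call(rbind, bad)
}

#' Read and write 6-column PED files
#'
#' Whitespace-delimited pedigree files with columns family, id, father,
#' mother, sex (1 = male, 2 = female, 0 = unknown) and affection
#' (2 = affected, 1 = unaffected, 0 = unknown); `0` marks a missing
#' parent.
#'
#' @param path file path.
#' @param genotyped optional character vector of ids to flag as genotyped.
#' @return `read_ped()`: a [pedigree()]. `write_ped()`: the path,
#'   invisibly.
#' @export
read_ped <- function(path, genotyped = character()) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 6L)
    stop_input("PED file must have 6 columns: ", path)
  names(tab)[1:6] <- c("fam", "id", "father", "mother", "sex", "aff")
  pedigree(
    id = tab$id, father = tab$father, mother = tab$mother,
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[tab$sex],
    affection = c("0" = "unknown", "1" = "unaffected",
                  "2" = "affected")[tab$aff],
    genotyped = tab$id %in% genotyped,
    name = tab$fam[1]
  )
}

#' @rdname read_ped
#' @param ped a [pedigree()] to write.
#' @export
write_ped <- function(ped, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affection]
  tab <- data.frame(attr(ped, "name") %||% "FAM", ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother), sex, aff)
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' The study family (reconstructed)
#'
#' The ten sampled members of the late-onset dementia family plus the
#' three married-in spouses required to close the pedigree. The topology
#' is a reconstruction from the published pedigree figure (the file is
#' named `*_synthetic.ped` for that reason): affected founder 102 with
#' children 200, 121, 124 (affected) and 122, 123 (elderly unaffected);
#' 201 and 202 are children of 200; 221 and 222 are children of 122.
#' Young unaffected members (201, 202, 221, 222) are coded unaffected,
#' matching the published analysis; married-in spouses are coded unknown.
#'
#' @param genotyped which members carry genotype data: `"wgs"` marks the
#'   six whole-genome-sequenced members (200, 102, 122, 123, 201, 202),
#'   `"all"` additionally marks the four Sanger-typed members
#'   (121, 124, 221, 222), `"none"` marks nobody.
#' @return A [pedigree()].
#' @export
ad_family <- function(genotyped = c("wgs", "all", "none")) {
  genotyped <- match.arg(genotyped)
  ids <- switch(genotyped,
                wgs = wgs_members(),
                all = c(wgs_members(), sanger_members()),
                none = character())
  read_ped(system.file("extdata", "ad_family_synthetic.ped",
                       package = "pedfunnel", mustWork = TRUE),
           genotyped = ids)
}

#' @rdname ad_family
#' @export
wgs_members <- function() c("200", "102", "122", "123", "201", "202")

#' @rdname ad_family
#' @export
sanger_members <- function() c("121", "124", "221", "222")
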