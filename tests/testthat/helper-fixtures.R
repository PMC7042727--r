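# Shared fixture builders and independent oracles. The brute-force
# likelihood oracle enumerates every ordered two-locus diplotype
# assignment directly and never calls the peeling engine.

nuclear_ped <- function(n_children = 2, affection = NULL) {
  ids <- c("F", "M", paste0("C", seq_len(n_children)))
  if (is.null(affection))
    affection <- c("affected", "unaffected",
                   rep("unaffected", n_children))
  pedigree(id = ids,
           father = c(NA, NA, rep("F", n_children)),
           mother = c(NA, NA, rep("M", n_children)),
           sex = c("male", "female", rep("male", n_children)),
           affection = affection)
}

# small variant_set from a genotype matrix given as list of rows
make_vs <- function(gt_rows, ids, chrom = "1", pos = NULL,
                    qual_rows = NULL) {
  n <- length(gt_rows)
  gt <- do.call(rbind, gt_rows)
  colnames(gt) <- ids
  if (is.null(qual_rows)) {
    qual <- ifelse(gt == "./.", "nocall", "VQHIGH")
  } else {
    qual <- do.call(rbind, qual_rows)
    colnames(qual) <- ids
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L
  variant_set(data.frame(chrom = rep(chrom, n), pos = pos,
                         ref = rep("A", n), alt = rep("G", n)),
              gt, qual)
}

# ---- independent brute-force two-locus likelihood oracle --------------

brute_likelihood <- function(ped, model, marker = NULL, theta = 0) {
  if (is.null(marker)) marker <- marker_locus("1", 1)
  k <- length(marker$alleles)
  H <- 2L * k
  G <- H * H
  d_of <- rep(1:2, each = k)
  m_of <- rep(seq_len(k), 2L)
  hp_of <- rep(seq_len(H), each = H)
  hm_of <- rep(seq_len(H), times = H)
  q <- c(1 - model$freq, model$freq)
  hapfreq <- q[d_of] * marker$freqs[m_of]
  prior <- hapfreq[hp_of] * hapfreq[hm_of]
  # gamete law derived independently: pick the disease-allele source
  # slot (1/2 each), marker travels with it w.p. 1 - theta
  gam <- matrix(0, G, H)
  for (g in seq_len(G)) {
    slots <- c(hp_of[g], hm_of[g])
    for (sd in 1:2) for (sm in 1:2) {
      h <- (d_of[slots[sd]] - 1L) * k + m_of[slots[sm]]
      w <- 0.5 * (if (sd == sm) 1 - theta else theta)
      gam[g, h] <- gam[g, h] + w
    }
  }
  nd <- (d_of[hp_of] == 2L) + (d_of[hm_of] == 2L)
  f <- model$penetrances
  penobs <- lapply(seq_len(nrow(ped)), function(i) {
    v <- switch(ped$affection[i], affected = f[nd + 1L],
                unaffected = 1 - f[nd + 1L], unknown = rep(1, G))
    id <- ped$id[i]
    if (id %in% names(marker$genotypes)) {
      ab <- match(strsplit(marker$genotypes[[id]], "/")[[1]],
                  marker$alleles)
      ok <- (m_of[hp_of] == ab[1] & m_of[hm_of] == ab[2]) |
        (m_of[hp_of] == ab[2] & m_of[hm_of] == ab[1])
      v <- v * as.numeric(ok)
    }
    v
  })
  trans <- array(0, c(G, G, G))       # [g_child, g_father, g_mother]
  for (gf in seq_len(G)) for (gm in seq_len(G)) {
    pr <- outer(gam[gf, ], gam[gm, ])     # [hp, hm]
    trans[, gf, gm] <- as.vector(t(pr))
  }
  n <- nrow(ped)
  fa_idx <- match(ped$father, ped$id)
  mo_idx <- match(ped$mother, ped$id)
  total <- 0
  chunk_iter <- function(fixed1) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(G)), n - 1L)))
    m <- cbind(rep(fixed1, nrow(grid)), grid)
    p <- rep(1, nrow(m))
    for (i in seq_len(n)) {
      p <- p * penobs[[i]][m[, i]]
      if (is.na(fa_idx[i])) p <- p * prior[m[, i]]
      else p <- p * trans[cbind(m[, i], m[, fa_idx[i]], m[, mo_idx[i]])]
    }
    sum(p)
  }
  if (n <= 5L) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(G)), n)))
    p <- rep(1, nrow(grid))
    for (i in seq_len(n)) {
      p <- p * penobs[[i]][grid[, i]]
      if (is.na(fa_idx[i])) p <- p * prior[grid[, i]]
      else p <- p * trans[cbind(grid[, i], grid[, fa_idx[i]],
                                grid[, mo_idx[i]])]
    }
    total <- sum(p)
  } else {
    for (v1 in seq_len(G)) total <- total + chunk_iter(v1)
  }
  total
}

# random loop-free pedigree with random phenotypes and marker data
random_pedigree_case <- function(size, k = 2, p_typed = 0.8) {
  id <- c("I1", "I2")
  father <- c(NA, NA); mother <- c(NA, NA)
  sex <- c("male", "female")
  couples <- list(c("I1", "I2"))
  nxt <- 3L
  while (length(id) < size) {
    new_id <- paste0("I", nxt); nxt <- nxt + 1L
    if (length(id) >= 3 && runif(1) < 0.25 && length(id) + 1 < size) {
      # marry a new founder to a random non-founder and give them a child
      cand <- id[!is.na(father)]
      if (length(cand) > 0) {
        p1 <- sample(cand, 1)
        sp <- paste0("I", nxt); nxt <- nxt + 1L
        id <- c(id, sp); father <- c(father, NA); mother <- c(mother, NA)
        sex <- c(sex, ifelse(sex[match(p1, id)] == "male",
                             "female", "male"))
        couples[[length(couples) + 1]] <-
          if (sex[match(p1, id)] == "male") c(p1, sp) else c(sp, p1)
      }
    }
    cp <- couples[[sample(length(couples), 1)]]
    id <- c(id, new_id)
    father <- c(father, cp[1]); mother <- c(mother, cp[2])
    sex <- c(sex, sample(c("male", "female"), 1))
  }
  n <- length(id)   # may overshoot `size` by one when a spouse married in
  ped <- pedigree(id, father[seq_len(n)], mother[seq_len(n)],
                  sex[seq_len(n)],
                  affection = sample(c("affected", "unaffected", "unknown"),
                                     n, replace = TRUE, prob = c(.3, .5, .2)))
  alleles <- as.character(seq_len(k))
  freqs <- rep(1 / k, k)
  typed <- ped$id[runif(n) < p_typed]
  genos <- setNames(vapply(typed, function(i)
    paste(sort(sample(alleles, 2, replace = TRUE)), collapse = "/"),
    character(1)), typed)
  list(ped = ped,
       marker = marker_locus(alleles, freqs, genos),
       model = disease_model(runif(1, 0.01, 0.3), runif(1, 0, 0.2),
                             runif(1, 0.5, 1), runif(1, 0.5, 1)))
}

expect_rel_equal <- function(x, y, tol = 1e-10) {
  if (abs(y) < 1e-280) expect_lt(abs(x), 1e-280)
  else expect_lt(abs(x - y) / abs(y), tol)
}
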