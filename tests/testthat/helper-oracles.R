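# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorised implementations.

oracle_pi <- function(aln, deletion = "complete") {
  n <- nrow(aln)
  valid <- matrix(aln %in% c("A", "C", "G", "T"), nrow = n)
  if (deletion == "complete") {
    keep <- rep(TRUE, ncol(aln))
    for (j in seq_len(ncol(aln))) {
      for (i in seq_len(n)) if (!valid[i, j]) keep[j] <- FALSE
    }
    L <- sum(keep)
    if (L == 0) stop("no sites")
    tot <- 0; np <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- 0
        for (k in which(keep)) if (aln[i, k] != aln[j, k]) d <- d + 1
        tot <- tot + d / L
        np <- np + 1
      }
    }
    tot / np
  } else {
    ratios <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- 0; L <- 0
        for (k in seq_len(ncol(aln))) {
          if (valid[i, k] && valid[j, k]) {
            L <- L + 1
            if (aln[i, k] != aln[j, k]) d <- d + 1
          }
        }
        ratios <- c(ratios, d / L)
      }
    }
    mean(ratios)
  }
}

# published TN93 closed form for one pair, base frequencies pooled over the
# pair's compared sites
oracle_tn93_pair <- function(s1, s2) {
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  s1 <- s1[ok]; s2 <- s2[ok]
  L <- length(s1)
  g <- table(factor(c(s1, s2), levels = c("A", "C", "G", "T"))) / (2 * L)
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- s1 != s2
  pur <- function(x) x %in% c("A", "G")
  P1 <- sum(diff & pur(s1) & pur(s2)) / L
  P2 <- sum(diff & !pur(s1) & !pur(s2)) / L
  Q <- sum(diff & (pur(s1) != pur(s2))) / L
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
}

random_alignment <- function(n, L, p_gap = 0.05) {
  x <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  gaps <- matrix(runif(n * L) < p_gap, nrow = n)
  x[gaps] <- sample(c("-", "N"), sum(gaps), replace = TRUE)
  rownames(x) <- paste0("s", seq_len(n))
  x
}

# two clades at `inter` divergence with `intra` within-clade noise, plus a
# mosaic recombinant switching from clade A to clade B after `bp` columns
two_clade_mosaic <- function(L = 1000, inter = 0.05, intra = 0.002, bp = 500,
                             n_clade = 3) {
  bases <- c("A", "C", "G", "T")
  mutate <- function(s, p) {
    hit <- runif(length(s)) < p
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1), character(1))
    s
  }
  ancA <- sample(bases, L, replace = TRUE)
  ancB <- mutate(ancA, inter)
  aln <- rbind(
    do.call(rbind, lapply(seq_len(n_clade), function(i) mutate(ancA, intra))),
    do.call(rbind, lapply(seq_len(n_clade), function(i) mutate(ancB, intra))),
    make_mosaic(ancA, ancB, bp)
  )
  rownames(aln) <- c(paste0("A", seq_len(n_clade)), paste0("B", seq_len(n_clade)), "R")
  aln
}
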