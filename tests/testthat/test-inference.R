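reg <- load_registry()
panel <- default_assay_panel(reg)

test_that("signatures are unions of haplotype content and within-haplotype links", {
  sig <- signature_of(reg, "cA01|tA01", panel = panel)
  st <- get_structure(reg, "cA01|tA01")
  expect_setequal(names(sig$presence)[sig$presence], st$gene_content)
  # homozygote indistinguishable from hemizygote
  sig2 <- signature_of(reg, "cB02|tA01", "cB02|tA01", panel)
  expect_identical(signature_of(reg, "cB02|tA01", panel = panel), sig2)
  # the classic phase ambiguity: same motif multiset, same signature
  a <- signature_of(reg, "cA01|tA01", "cB01|tB01", panel)
  b <- signature_of(reg, "cA01|tB01", "cB01|tA01", panel)
  expect_identical(a, b)
  expect_error(signature_of(reg, "cX99|tA01"), "unknown motif")
})

test_that("compatible_pairs reproduces the query signature (oracle re-check)", {
  set.seed(7)
  pairs <- list(c("cA01|tA01", "cA01|tA01"),
                c("cA01|tA01", "cB01|tB01"),
                c("cB02|tA01", "cB03|tA01"))
  for (p in pairs) {
    sig <- signature_of(reg, p[1], p[2], panel)
    hits <- compatible_pairs(reg, sig, panel)
    expect_true(any(vapply(hits, setequal, logical(1), y = p)))
    for (h in hits) {
      expect_identical(kirhaplo:::signature_key(signature_of(reg, h[1], h[2], panel)),
                       kirhaplo:::signature_key(sig))
    }
  }
  # homozygous cA01|tA01 matches only itself
  sig <- signature_of(reg, "cA01|tA01", "cA01|tA01", panel)
  expect_equal(compatible_pairs(reg, sig, panel), list(c("cA01|tA01", "cA01|tA01")))
  # an unmatched signature returns the empty list
  none <- structure(list(presence = setNames(c(TRUE, rep(FALSE, 12)),
                                             panel$presence),
                         links = character(0)), class = "kir_signature")
  expect_equal(compatible_pairs(reg, none, panel), list())
})

test_that("the two classic phase-ambiguity classes appear; cross-central links resolve them", {
  classes <- enumerate_ambiguity_classes(reg, panel)
  keyed <- lapply(classes, function(cl) sort(vapply(cl, paste, character(1),
                                                   collapse = "-")))
  expect_true(list(c("cA01|tA01-cB01|tB01", "cA01|tB01-cB01|tA01")) %in% keyed ||
                any(vapply(keyed, identical,
                           logical(1), y = c("cA01|tA01-cB01|tB01",
                                             "cA01|tB01-cB01|tA01"))))
  expect_true(any(vapply(keyed, identical, logical(1),
                         y = c("cA01|tA01-cB02|tB01", "cA01|tB01-cB02|tA01"))))
  # junction-spanning assays phase cen against tel wherever the
  # junction-adjacent genes differ: cB02 ends in 2DL2 (vs 2DL1 for
  # cA01/cB01), so the cA01/cB02 swap class is resolved; the cA01/cB01
  # class persists because both motifs end in 2DL1
  xc <- default_assay_panel(reg, cross_central = TRUE)
  classes_xc <- enumerate_ambiguity_classes(reg, xc)
  keyed_xc <- lapply(classes_xc, function(cl) vapply(cl, paste, character(1),
                                                     collapse = "-"))
  expect_false(any(vapply(keyed_xc, function(k)
    "cA01|tB01-cB02|tA01" %in% k && "cA01|tA01-cB02|tB01" %in% k, logical(1))))
  expect_true(any(vapply(keyed_xc, function(k)
    "cA01|tB01-cB01|tA01" %in% k && "cA01|tA01-cB01|tB01" %in% k, logical(1))))
  # two haplotypes differing at an assayed locus are never confused
  expect_equal(enumerate_ambiguity_classes(reg, panel,
                                           structures = c("cA01|tA01", "cB01|tB01")),
               list())
})

test_that("EM equals direct allele counting when signatures are unambiguous", {
  two <- c("cA01|tA01", "cB01|tB01")
  sig_hom <- signature_of(reg, two[1], two[1], panel)
  sig_het <- signature_of(reg, two[1], two[2], panel)
  obs <- kir_cohort(
    id = paste0("i", 1:100),
    population = rep("p", 100),
    signatures = c(rep(list(sig_hom), 60), rep(list(sig_het), 40))
  )
  est <- em_estimate(obs, reg, panel, structures = two, other_class = FALSE)
  expect_equal(unname(est$freqs[two]), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(est$unresolved_chromosomes, 0)
  # all-homozygous cohort concentrates on one haplotype
  obs1 <- kir_cohort("a", "p", list(sig_hom))
  est1 <- em_estimate(obs1, reg, panel, structures = two, other_class = FALSE)
  expect_equal(unname(est1$freqs[two[1]]), 1.0)
})

test_that("EM matches an independent fixed-point oracle on ambiguous cohorts", {
  sig_amb <- signature_of(reg, "cA01|tA01", "cB01|tB01", panel)   # 2 candidate pairs
  sig_anchor1 <- signature_of(reg, "cA01|tA01", "cA01|tA01", panel)
  # the cB01/cB03 heterozygote is uniquely identified: each motif carries a
  # linking assay the other lacks
  sig_anchor2 <- signature_of(reg, "cB01|tA01", "cB03|tA01", panel)
  counts <- c(30, 50, 20)
  obs <- kir_cohort(
    id = paste0("i", 1:100), population = rep("p", 100),
    signatures = c(rep(list(sig_amb), counts[1]),
                   rep(list(sig_anchor1), counts[2]),
                   rep(list(sig_anchor2), counts[3]))
  )
  S <- reg$structures
  est <- em_estimate(obs, reg, panel, tol = 1e-12, other_class = FALSE)

  # independent fixed-point iteration over explicitly enumerated candidates
  cands <- lapply(list(sig_amb, sig_anchor1, sig_anchor2), function(s)
    compatible_pairs(reg, s, panel))
  f <- setNames(rep(1 / length(S), length(S)), S)
  for (it in 1:3000) {
    cnt <- setNames(numeric(length(S)), S)
    for (g in seq_along(cands)) {
      w <- sapply(cands[[g]], function(p)
        if (p[1] == p[2]) f[p[1]]^2 else 2 * f[p[1]] * f[p[2]])
      w <- w / sum(w)
      for (k in seq_along(cands[[g]])) {
        p <- cands[[g]][[k]]
        cnt[p[1]] <- cnt[p[1]] + counts[g] * w[k]
        cnt[p[2]] <- cnt[p[2]] + counts[g] * w[k]
      }
    }
    fn <- cnt / sum(cnt)
    if (max(abs(fn - f)) < 1e-14) break
    f <- fn
  }
  expect_equal(est$freqs[S], f, tolerance = 1e-8)
  # ambiguous mass split towards the anchored haplotypes
  expect_gt(est$freqs[["cA01|tA01"]], est$freqs[["cA01|tB01"]])
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(est$loglik) >= -1e-9))
})

test_that("unregistered haplotypes are modelled as an explicit other class", {
  set.seed(11)
  co <- simulate_cohort(n = 150, registry = reg, seed = 303)
  est <- em_estimate(co, reg, panel)
  expect_true("other" %in% names(est$freqs))
  expect_equal(sum(est$freqs), 1, tolerance = 1e-9)
  expect_gt(est$unresolved_chromosomes, 0)
  # strict exclusion mode drops unmatched individuals entirely
  est2 <- em_estimate(co, reg, panel, other_class = FALSE)
  expect_false("other" %in% names(est2$freqs))
  expect_equal(est2$unresolved_chromosomes %% 2, 0)
  expect_error(em_estimate(kir_cohort("x", "p", list(
    structure(list(presence = setNames(rep(FALSE, 13), panel$presence),
                   links = character(0)), class = "kir_signature"))),
    reg, panel, other_class = FALSE), "no individual")
})

test_that("frequency tables pool counts and round percentages to one decimal", {
  m <- rbind(
    "cA01|tA01" = c(52, 61, 59, 60),
    "cA01|tB01" = c(5, 15, 15, 9),
    "cB01|tB01" = c(2, 1, 1, 6),
    "cB02|tA01" = c(6, 5, 8, 15),
    "cB01|tA01" = c(14, 2, 8, 4),
    "cB02|tB01" = c(2, 6, 4, 1),
    "cB03|tA01" = c(2, 0, 0, 0),
    "other"     = c(13, 6, 1, 1)
  )
  tab <- pool_frequency_counts(m)
  expect_equal(tab$total[tab$haplotype == "cA01|tA01"], 232)
  expect_equal(tab$percent[tab$haplotype == "cA01|tA01"], 60.4)
  expect_equal(tab$percent[tab$haplotype == "other"], 5.5)
  # degenerate single-population all-homozygote cohort reports 100%
  sig <- signature_of(reg, "cA01|tA01", "cA01|tA01", panel)
  obs <- kir_cohort(paste0("i", 1:5), rep("p", 5), rep(list(sig), 5))
  est <- em_estimate(obs, reg, panel, structures = c("cA01|tA01", "cB01|tB01"),
                     other_class = FALSE)
  rep_tab <- frequency_report(est, obs, reg, panel)
  expect_equal(rep_tab$percent[rep_tab$haplotype == "cA01|tA01"], 100.0)
  expect_equal(sum(rep_tab$total), 10)
})
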