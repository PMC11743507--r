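# Differential genera, key microbes, core/specific partition, abundance
# ratios, and the correlation network.

two_condition_rel <- function() {
  tb <- tibble::tibble(
    sample_id = sprintf("s%d", 1:10),
    gA = c(0.10, 0.11, 0.09, 0.10, 0.10, 0.20, 0.21, 0.19, 0.20, 0.20),
    gB = rep(0.5, 10),
    gC = c(0.40, 0.39, 0.41, 0.40, 0.40, 0.30, 0.29, 0.31, 0.30, 0.30))
  meta <- tibble::tibble(sample_id = tb$sample_id,
                         mouse_id = tb$sample_id,
                         group = rep(c("A", "B"), each = 5), week = 10L)
  list(rel = tb, meta = meta)
}

test_that("differential_genera matches the Welch oracle on a toy contrast", {
  fx <- two_condition_rel()
  res <- differential_genera(fx$rel, fx$meta, "A", "B", pseudocount = 0)
  ga <- res[res$genus == "gA", ]
  # oracle: direct Welch test on the same vectors
  oracle <- t.test(fx$rel$gA[1:5], fx$rel$gA[6:10])$p.value
  expect_equal(ga$p_value, oracle, tolerance = 1e-12)
  expect_true(ga$significant)
  expect_equal(ga$log2_ratio, log2(0.10 / 0.20), tolerance = 1e-3)
  # identical values in both conditions: p in the non-significant regime
  gb <- res[res$genus == "gB", ]
  expect_false(gb$significant)
  expect_equal(gb$log2_ratio, 0)
  # sorted by p
  expect_true(!is.unsorted(res$p_value))
  # Student variant and Kruskal option run
  st <- differential_genera(fx$rel, fx$meta, "A", "B", var_equal = TRUE)
  expect_equal(st$genus, res$genus)
  kw <- differential_genera(fx$rel, fx$meta, "A", "B", test = "kruskal")
  oracle_kw <- kruskal.test(list(fx$rel$gA[1:5], fx$rel$gA[6:10]))$p.value
  expect_equal(kw$p_value[kw$genus == "gA"], oracle_kw, tolerance = 1e-12)
  # a condition with < 2 samples errors
  expect_error(
    differential_genera(fx$rel[c(1, 6:10), ], fx$meta, "A", "B"),
    class = "ms_validation_error")
})

test_that("min_prevalence excludes rare genera and reports them", {
  fx <- two_condition_rel()
  fx$rel$gRare <- c(0.01, rep(0, 9))
  res <- differential_genera(fx$rel, fx$meta, "A", "B", min_prevalence = 0.5)
  expect_false("gRare" %in% res$genus)
  expect_equal(attr(res, "excluded"), "gRare")
})

test_that("key_microbes is a commutative, idempotent intersection", {
  mk <- function(genera, sig) tibble::tibble(genus = genera,
                                             significant = sig)
  a <- mk(c("A", "B", "C", "D"), c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c("A", "B", "C", "D"), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(key_microbes(a, b), c("B", "C"))
  expect_equal(key_microbes(b, a), key_microbes(a, b))
  expect_equal(key_microbes(a, a), sort(a$genus[a$significant]))
  none <- mk(c("A", "B"), c(FALSE, FALSE))
  expect_equal(key_microbes(a, none), character(0))
})

test_that("core_specific partitions genera as set intersection/difference", {
  # 4 groups sharing exactly 23 genera, plus one specific genus each
  core_genera <- sprintf("core_%02d", 1:23)
  groups <- c("G1", "G2", "G3", "G4")
  rows <- purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[i]
    base <- setNames(rep(1, 23), core_genera)
    spec <- setNames(rep(0, 4), sprintf("spec_%d", 1:4))
    spec[i] <- 1
    vals <- c(base, spec)
    out <- tibble::as_tibble(as.list(vals / sum(vals)))
    dplyr::bind_cols(tibble::tibble(sample_id = paste0(g, "_s1")), out)
  })
  meta <- tibble::tibble(sample_id = rows$sample_id,
                         mouse_id = rows$sample_id,
                         group = groups, week = 10L)
  part <- core_specific(rows, meta)
  expect_length(part$core, 23)
  expect_setequal(part$core, core_genera)
  for (i in seq_along(groups)) {
    expect_equal(part$specific[[groups[i]]], sprintf("spec_%d", i))
  }
  # invariants: core in every group set, specific disjoint from core
  for (g in groups) {
    expect_true(all(part$core %in% part$per_group[[g]]))
    expect_length(intersect(part$specific[[g]], part$core), 0)
  }
  td <- tidy(part)
  expect_equal(sum(td$status == "core"), 23)

  # all genera everywhere: core = all, specific empty
  fx <- two_condition_rel()
  all_part <- core_specific(fx$rel, fx$meta)
  expect_setequal(all_part$core, c("gA", "gB", "gC"))
  expect_true(all(lengths(all_part$specific) == 0))
})

test_that("abundance_ratio applies the pseudocount arithmetic exactly", {
  fx <- two_condition_rel()
  r <- abundance_ratio(fx$rel, fx$meta, "B", "A", pseudocount = 0)
  expect_equal(r$ratio[r$genus == "gA"], 2, tolerance = 1e-12)
  expect_equal(r$ratio[r$genus == "gB"], 1, tolerance = 1e-12)
  # zero denominator with a pseudocount
  tb <- tibble::tibble(sample_id = c("x", "y"), g = c(1e-3, 0))
  meta <- tibble::tibble(sample_id = c("x", "y"), mouse_id = c("x", "y"),
                         group = c("post", "pre"), week = 10L)
  rr <- abundance_ratio(tb, meta, "post", "pre", pseudocount = 1e-6)
  expect_equal(rr$ratio, (1e-3 + 1e-6) / 1e-6, tolerance = 1e-12)
  expect_error(abundance_ratio(tb, meta, "post", "pre", pseudocount = -1),
               class = "ms_parameter_error")
})

test_that("correlation_network retains exact relationships and is symmetric", {
  set.seed(8)
  rel <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                        g1 = c(2, 4, 6, 8) / 20,
                        g2 = stats::runif(4))
  feats <- tibble::tibble(sample_id = rel$sample_id, bw = c(1, 2, 3, 4))
  net <- correlation_network(rel, feats)
  edge <- net[net$source == "g1" & net$target == "bw" |
                net$source == "bw" & net$target == "g1", ]
  expect_equal(nrow(edge), 1)
  expect_equal(edge$r, 1, tolerance = 1e-10)
  # no self-edges; each unordered pair appears at most once
  expect_true(all(net$source != net$target))
  keys <- apply(cbind(net$source, net$target), 1,
                function(x) paste(sort(x), collapse = "|"))
  expect_false(any(duplicated(keys)))
  # symmetric under exchanging the node roles (column order of the input)
  net_swapped <- correlation_network(rel[, c(1, 3, 2)], feats)
  k2 <- apply(cbind(net_swapped$source, net_swapped$target), 1,
              function(x) paste(sort(x), collapse = "|"))
  expect_setequal(keys, k2)
  # constant columns are skipped with a warning
  rel_const <- dplyr::mutate(rel, gconst = 0.25)
  expect_warning(correlation_network(rel_const, feats), "constant")
  # unjoinable samples are listed
  expect_error(correlation_network(rel, feats[1:3, ]),
               class = "ms_join_error")
})

test_that("BH-adjusted edges are a subset of the unadjusted edges", {
  set.seed(21)
  n <- 20
  rel <- matrix_to_tibble_for_test(matrix(stats::runif(n * 12), n))
  raw <- correlation_network(rel, alpha = 0.2, adjust = "none")
  bh <- correlation_network(rel, alpha = 0.2, adjust = "bh")
  key <- function(x) paste(x$source, x$target)
  expect_true(all(key(bh) %in% key(raw)))
})

test_that("differential recovery on simulated effects meets the module
           contract", {
  # delta = 1, n = 20/group: at least 80% of the truly shifted genera are
  # recovered; BH on the unshifted genera keeps false discoveries <= 10%
  recov <- vapply(1:5, function(i) {
    d <- shifted_design(seed = 300 + i, delta = 1, n_mice = 20)
    s <- simulate_counts(d)
    rel <- to_relative(s$counts)
    res <- differential_genera(rel, s$metadata, "B", "A")
    truly <- s$ground_truth$genera_truly_shifted
    hits <- sum(res$significant & res$genus %in% truly)
    fp_bh <- sum(p.adjust(res$p_value[!res$genus %in% truly], "BH") < 0.05)
    c(hits / length(truly), fp_bh / sum(!res$genus %in% truly))
  }, numeric(2))
  expect_gte(mean(recov[1, ]), 0.8)
  expect_lte(mean(recov[2, ]), 0.1)
})
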