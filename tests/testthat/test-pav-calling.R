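test_that("ratio screen flags the quoted patterns and matches brute force", {
  lib <- stats::setNames(rep(1e7, 5), LETTERS[1:5])
  mk <- function(...) count_matrix(matrix(c(...), 1, 5,
                                          dimnames = list("g", LETTERS[1:5])), lib)
  th <- pav_thresholds()
  expect_equal(screen_ratio(normalize_counts(mk(10, 10, 10, 10, 10)), th),
               character(0))
  expect_equal(screen_ratio(normalize_counts(mk(0, 20, 18, 22, 19)), th), "g")
  # a zero against unsupported depth is not a candidate
  expect_equal(screen_ratio(normalize_counts(mk(0, 3, 4, 3, 5)), th),
               character(0))
  expect_error(screen_ratio(normalize_counts(
    count_matrix(matrix(5, 1, 1, dimnames = list("g", "A")), c(A = 1e6)))),
    "two cultivars")

  for (seed in 1:4) {
    cm <- rand_counts(seed = seed)
    expect_setequal(screen_ratio(normalize_counts(cm), th), oracle_ratio(cm))
  }
})

test_that("absolute screen uses strict raw-count bounds", {
  th <- pav_thresholds()
  mk <- function(...) {
    v <- c(...)
    count_matrix(matrix(v, 1, length(v),
                        dimnames = list("g", LETTERS[seq_along(v)])),
                 stats::setNames(rep(1e6, length(v)), LETTERS[seq_along(v)]))
  }
  expect_equal(screen_absolute(mk(5, 30), th), "g")       # <6 and >29
  expect_equal(screen_absolute(mk(6, 29), th), character(0))
  expect_equal(screen_absolute(mk(6, 300), th), character(0))
  expect_equal(screen_absolute(mk(5, 29), th), character(0))
  expect_equal(screen_absolute(mk(0, 0, 0, 0, 0), th), character(0))
})

test_that("low-support filter discards only genes weak in every cultivar", {
  m <- matrix(c(9, 9, 9, 9, 9,
                9, 10, 0, 0, 0,
                50, 60, 40, 80, 90), 3, 5, byrow = TRUE,
              dimnames = list(c("weak", "edge", "strong"), LETTERS[1:5]))
  cm <- count_matrix(m, stats::setNames(rep(1e6, 5), LETTERS[1:5]))
  flt <- filter_low_support(cm, rownames(m))
  expect_equal(flt$discarded, "weak")
  expect_setequal(flt$retained, c("edge", "strong"))
  expect_setequal(c(flt$retained, flt$discarded), rownames(m))
  expect_length(intersect(flt$retained, flt$discarded), 0)
})

test_that("candidate merging keeps provenance and set arithmetic", {
  m <- merge_candidates(c("a", "b"), c("c", "d"))
  expect_equal(nrow(m), 4)
  m2 <- merge_candidates(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(nrow(m2), 4)  # |A| + |B| - |A intersect B|
  expect_equal(m2$screens[m2$gene_id == "b"], "ratio,absolute")
  manual <- withr::local_tempfile(lines = c("z", ""))
  m3 <- merge_candidates(c("a"), character(0), manual)
  expect_equal(m3$screens[m3$gene_id == "z"], "manual")
  expect_equal(nrow(merge_candidates("a", "a", NULL)), 1)
})

test_that("absence review follows the relative-depth and breadth windows", {
  lib <- stats::setNames(rep(1e7, 5), LETTERS[1:5])
  cm <- count_matrix(matrix(c(0, 100, 90, 95, 100,
                              40, 100, 95, 98, 100), 2, 5, byrow = TRUE,
                            dimnames = list(c("g1", "g2"), LETTERS[1:5])), lib)
  nm <- normalize_counts(cm)
  bm <- breadth_matrix(matrix(c(0, 1, 1, 1, 1,
                                0.5, 1, 1, 1, 1), 2, 5, byrow = TRUE,
                              dimnames = dimnames(cm$counts)))
  calls <- assign_absences(c("g1", "g2"), cm, nm, bm)
  g1 <- calls[calls$gene_id == "g1", ]
  expect_equal(g1$status[g1$cultivar == "A"], "absent")
  expect_true(all(g1$status[g1$cultivar != "A"] == "present"))
  # norm 40 vs max 100 with breadth 0.5: inside the partial window
  g2 <- calls[calls$gene_id == "g2", ]
  expect_equal(g2$status[g2$cultivar == "A"], "partial")

  # without breadth, partial calling is disabled with a warning
  expect_warning(calls2 <- assign_absences(c("g1", "g2"), cm, nm, NULL),
                 "breadth")
  expect_equal(calls2$status[calls2$gene_id == "g1" & calls2$cultivar == "A"],
               "absent")
  expect_false("partial" %in% calls2$status)
  # candidates with no affected cultivar are dropped
  expect_false("g2" %in% calls2$gene_id)
})

test_that("screens are invariant to rescaling a cultivar's depth", {
  cm <- rand_counts(seed = 7)
  # keep zero cells zero and supported cells comfortably supported
  m <- cm$counts
  m[m > 0 & m < 40] <- m[m > 0 & m < 40] + 40
  m[, "C"] <- m[, "C"] * 2L   # even, so halving stays integer-exact
  cm <- count_matrix(m, cm$library_sizes)
  th <- pav_thresholds()
  base <- screen_ratio(normalize_counts(cm), th)
  for (k in c(0.5, 2, 3)) {
    m2 <- m; m2[, "C"] <- m2[, "C"] * k
    lib2 <- cm$library_sizes; lib2["C"] <- lib2["C"] * k
    scaled <- screen_ratio(normalize_counts(count_matrix(m2, lib2)), th)
    expect_setequal(scaled, base)
  }
})

test_that("reducing an absent gene's count never resurrects it", {
  cm <- rand_counts(seed = 3)
  nm <- normalize_counts(cm)
  cand <- screen_ratio(nm)
  suppressWarnings(calls <- assign_absences(cand, cm, nm, NULL))
  ab <- calls[calls$status == "absent", ][1, ]
  m2 <- cm$counts
  m2[ab$gene_id, ab$cultivar] <- floor(m2[ab$gene_id, ab$cultivar] / 2)
  cm2 <- count_matrix(m2, cm$library_sizes)
  suppressWarnings(calls2 <- assign_absences(cand, cm2,
                                             normalize_counts(cm2), NULL))
  expect_equal(calls2$status[calls2$gene_id == ab$gene_id &
                               calls2$cultivar == ab$cultivar], "absent")
})

test_that("reference absences are artifact-flagged and parent-checked", {
  calls <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 3),
    cultivar = rep(c("REF", "P1", "P2"), 2),
    status = c("absent", "present", "present",
               "absent", "absent", "present"),
    screens = "ratio", raw = 0, norm = 0, breadth = NA_real_,
    artifact_flag = FALSE, stringsAsFactors = FALSE)
  out <- flag_reference_artifacts(calls, "REF", parents = c("P1", "P2"))
  expect_true(all(out$artifact_flag[out$cultivar == "REF"]))
  expect_false(any(out$artifact_flag[out$cultivar != "REF"]))
  # g1 absent in reference, present in both parents: clear false positive
  expect_true(out$parent_inconsistent[out$gene_id == "g1" &
                                        out$cultivar == "REF"])
  expect_false(any(out$parent_inconsistent[out$gene_id == "g2"]))
  none <- flag_reference_artifacts(calls[calls$status == "present", ], "REF")
  expect_false(any(none$artifact_flag))
})

test_that("summary tallies events, histogram and per-cultivar shares", {
  one <- data.frame(gene_id = "g1", cultivar = "A", status = "absent",
                    screens = "ratio", raw = 0, norm = 0,
                    breadth = NA_real_, artifact_flag = FALSE)
  s <- summarize_pav(one, 100)
  expect_equal(s$n_events, 1)
  expect_equal(s$genes_by_n_absent_cultivars, c(`1` = 1L))
  expect_equal(s$n_pav_genes, 1)
  expect_equal(s$pav_fraction_of_complement, 1)

  # partials count as events; histogram sums to the PAV gene count
  calls <- rbind(one,
                 data.frame(gene_id = "g2", cultivar = c("A", "B"),
                            status = c("absent", "partial"), screens = "ratio",
                            raw = 0, norm = 0, breadth = 0.5,
                            artifact_flag = FALSE))
  s2 <- summarize_pav(calls, 100)
  expect_equal(s2$n_events, 3)
  expect_equal(s2$genes_by_n_absent_cultivars, c(`1` = 1L, `2` = 1L))
  expect_equal(sum(s2$genes_by_n_absent_cultivars), s2$n_pav_genes)
  expect_equal(s2$events_per_cultivar, c(A = 2L, B = 1L))
})

test_that("final PAV set is nested in candidates and the annotation", {
  p <- small_params(n_genes = 2500, seed = 19)
  sim <- simulate_cohort(p, withr::local_tempdir())
  pav <- call_pav(sim$counts, sim$breadth, reference = "DHL92")
  norm <- normalize_counts(sim$counts)
  merged <- merge_candidates(screen_ratio(norm), screen_absolute(sim$counts))
  expect_true(all(unique(pav$calls$gene_id) %in% merged$gene_id))
  expect_true(all(merged$gene_id %in% sim$genes$gene_id))
})

test_that("planted deletions are recovered on a clean cohort", {
  p <- sim_params(n_genes = 3000, n_scaffolds = 8, seed = 27,
                  overdispersion = 0, breadth_noise = 0,
                  background_mismap_rate = 0)
  sim <- simulate_cohort(p, withr::local_tempdir())
  pav <- call_pav(sim$counts, sim$breadth, reference = "DHL92")
  calls <- pav$calls
  key <- function(df) paste(df$gene_id, df$cultivar)

  full <- sim$truth[sim$truth$kind == "full", ]
  expect_true(all(key(full) %in% key(calls[calls$status == "absent", ])))
  deep_partial <- sim$truth[sim$truth$kind == "partial" &
                              sim$truth$retained_fraction < 0.4, ]
  expect_true(all(key(deep_partial) %in%
                    key(calls[calls$status == "partial", ])))
  # nothing called affected outside the planted truth
  affected <- calls[calls$status != "present", ]
  expect_true(all(key(affected) %in% key(sim$truth)))
})
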