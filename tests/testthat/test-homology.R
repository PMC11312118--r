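# Hit-table parsing, best-hit and BBH rules, and the paralogy threshold scan,
# cross-checked against brute-force references.

mini_table <- function(rows) {
  # rows: data.frame(query_id, subject_id, evalue, bitscore)
  n <- nrow(rows)
  hit_table(data.frame(
    query_id = rows$query_id, subject_id = rows$subject_id,
    pct_identity = 80, align_len = 100L, mismatches = 20L, gap_opens = 0L,
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = rows$evalue, bitscore = rows$bitscore,
    stringsAsFactors = FALSE), species_from_prefix())
}

test_that("outfmt-6 parsing validates shape and numbers", {
  tmp <- withr::local_tempdir()
  good <- file.path(tmp, "good.tsv")
  writeLines("a_1\tb_1\t85.2\t120\t17\t1\t1\t120\t3\t122\t3e-50\t210", good)
  tab <- read_hit_table(good, species_from_prefix())
  expect_equal(nrow(tab$hits), 1)
  expect_equal(tab$hits$evalue, 3e-50)
  expect_equal(unname(tab$species_of[c("a_1", "b_1")]), c("a", "b"))

  bad <- file.path(tmp, "bad.tsv")
  writeLines(c("a_1\tb_1\t85.2\t120\t17\t1\t1\t120\t3\t122\t3e-50\t210",
               paste(rep("x", 11), collapse = "\t")), bad)
  expect_error(read_hit_table(bad, species_from_prefix()), "line 2")

  expect_error(hit_table(data.frame(query_id = "a"), NULL), "lacks columns")
  expect_error(
    mini_table(data.frame(query_id = "weird id", subject_id = "b_1",
                          evalue = 1e-10, bitscore = 50)),
    NA)  # prefix rule still maps it ("weird")
  expect_error(
    hit_table(data.frame(query_id = "a", subject_id = "b", pct_identity = 80,
                         align_len = 1L, mismatches = 0L, gap_opens = 0L,
                         q_start = 1L, q_end = 1L, s_start = 1L, s_end = 1L,
                         evalue = 1e-5, bitscore = 10),
              c(a = "sp1")),
    "without a species mapping")
})

test_that("best_hit applies the e-value, bitscore, id tie-break chain", {
  tab <- mini_table(data.frame(
    query_id = c("a_1", "a_1", "a_2", "a_2", "a_3"),
    subject_id = c("b_1", "b_2", "b_1", "b_2", "b_1"),
    evalue = c(1e-50, 1e-10, 1e-20, 1e-20, 1e-20),
    bitscore = c(200, 80, 180, 210, 100)))
  expect_equal(best_hit(tab, "a_1", "b"), "b_1")          # unique minimum
  expect_equal(best_hit(tab, "a_2", "b"), "b_2")          # bitscore tie-break
  expect_equal(best_hit(tab, "a_1", "c"), NA_character_)  # no hits there
  expect_equal(best_hit(tab, "a_1", "b", evalue_ceiling = 1e-60), NA_character_)
  # full tie falls back to lexicographic subject
  tie <- mini_table(data.frame(query_id = c("a_1", "a_1"),
                               subject_id = c("b_2", "b_1"),
                               evalue = 1e-9, bitscore = 55))
  expect_equal(best_hit(tie, "a_1", "b"), "b_1")
})

test_that("bbh_orthologs emits exactly the mutual best pairs", {
  tab <- mini_table(data.frame(
    query_id = c("a_1", "b_1", "a_2"),
    subject_id = c("b_1", "a_1", "b_1"),
    evalue = c(1e-50, 1e-48, 1e-10),
    bitscore = c(200, 195, 80)))
  bb <- bbh_orthologs(tab, "a", "b")
  expect_equal(nrow(bb), 1)
  expect_equal(bb$gene_a, "a_1")
  expect_equal(bb$gene_b, "b_1")
  expect_equal(bb$evalue_ab, 1e-50)
  expect_equal(bb$evalue_ba, 1e-48)

  # one side above the ceiling kills the pair
  high <- mini_table(data.frame(query_id = c("a_1", "b_1"),
                                subject_id = c("b_1", "a_1"),
                                evalue = c(1e-50, 1e-3), bitscore = 100))
  expect_equal(nrow(bbh_orthologs(high, "a", "b")), 0)

  expect_error(bbh_orthologs(tab, "a", "a"), "differ")
})

test_that("BBH equals the brute-force oracle and is symmetric on synthetic tables", {
  for (seed in 1:8) {
    cfg <- synth_config(n_species = 3, n_families = 12, dup_rate = 0.4,
                        seed = seed)
    tab <- simulate_hit_table(simulate_families(cfg), cfg)
    for (pair in list(c("sp01", "sp02"), c("sp02", "sp03"))) {
      got <- bbh_orthologs(tab, pair[1], pair[2])
      expect_setequal(bbh_pairs_as_keys(got), oracle_bbh(tab, pair[1], pair[2]))
      # symmetry: swapping the species gives the same unordered pairs
      rev <- bbh_orthologs(tab, pair[2], pair[1])
      expect_setequal(paste(got$gene_a, got$gene_b),
                      paste(rev$gene_b, rev$gene_a))
      # each gene in at most one pair per species pair
      expect_false(anyDuplicated(got$gene_a) > 0)
      expect_false(anyDuplicated(got$gene_b) > 0)
    }
  }
})

test_that("paralog edges equal the brute-force double loop and grow monotonically", {
  for (seed in 1:8) {
    cfg <- synth_config(n_species = 2, n_families = 15, dup_rate = 0.5,
                        seed = seed)
    tab <- simulate_hit_table(simulate_families(cfg), cfg)
    for (cutoff in c(1e-50, 1e-20, 1e-5)) {
      got <- paralog_edges(tab, "sp01", cutoff)
      expect_setequal(paralog_edges_as_keys(got),
                      oracle_paralog_edges(tab, "sp01", cutoff))
      expect_false(any(got$gene_a == got$gene_b))
    }
    strict <- paralog_edges_as_keys(paralog_edges(tab, "sp01", 1e-50))
    loose <- paralog_edges_as_keys(paralog_edges(tab, "sp01", 1e-5))
    expect_true(all(strict %in% loose))
  }
})

test_that("the threshold scan reproduces the worked component counts", {
  tab <- mini_table(data.frame(
    query_id = c("a_1", "b_1", "a_2"),
    subject_id = c("a_2", "b_2", "b_1"),
    evalue = c(1e-50, 1e-60, 1e-8),
    bitscore = c(150, 160, 40)))
  scan <- paralog_threshold_scan(tab, c("a", "b"), grid = c(1e-5, 1e-10))
  expect_equal(unname(scan$count_at), c(2, 2))
  # per species the a-b cross-species hit is irrelevant
  scan_a <- paralog_threshold_scan(tab, "a", grid = c(1e-5, 1e-10))
  expect_equal(unname(scan_a$count_at), c(1, 1))
  expect_equal(scan_a$chosen_cutoff, 1e-10)  # tie -> most stringent

  # only self-hits: zero everywhere, smallest grid value chosen
  selfy <- mini_table(data.frame(query_id = "a_1", subject_id = "a_1",
                                 evalue = 0, bitscore = 500))
  s0 <- paralog_threshold_scan(selfy, "a", grid = c(1e-5, 1e-10))
  expect_equal(unname(s0$count_at), c(0, 0))
  expect_equal(s0$chosen_cutoff, 1e-10)

  expect_error(paralog_threshold_scan(tab, "zz"), "absent")
  expect_error(paralog_threshold_scan(tab, "a", grid = 1e-5), "2 cutoffs")
})

test_that("incremental scan counts equal a naive per-cutoff recount", {
  for (seed in 1:6) {
    cfg <- synth_config(n_species = 2, n_families = 15, dup_rate = 0.5,
                        seed = seed)
    tab <- simulate_hit_table(simulate_families(cfg), cfg)
    grid <- 10^seq(-60, -4, by = 4)
    scan <- paralog_threshold_scan(tab, "sp01", grid = grid)
    naive <- vapply(sort(grid), function(cc)
      oracle_dup_network_count(tab, "sp01", cc), integer(1))
    expect_equal(unname(scan$count_at), unname(naive))
  }
})

test_that("the scan recovers the planted gap and duplication-group count", {
  cfg <- synth_config(seed = 77)
  truth <- simulate_families(cfg)
  tab <- simulate_hit_table(truth, cfg)
  dg <- duplication_groups(truth)
  fam_of <- setNames(truth$members$family_id, truth$members$gene_id)
  for (sp in cfg$species) {
    scan <- paralog_threshold_scan(tab, sp)
    expect_equal(max(scan$count_at), sum(dg$species == sp))
    expect_equal(unname(scan$count_at[sprintf("%g", scan$chosen_cutoff)]),
                 max(scan$count_at))
    # chosen cutoff excludes every background (cross-family) pair
    pe <- paralog_edges(tab, sp, scan$chosen_cutoff)
    expect_true(all(fam_of[pe$gene_a] == fam_of[pe$gene_b]))
    expect_lt(scan$chosen_cutoff, cfg$background_evalue_range[1])
  }
})
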