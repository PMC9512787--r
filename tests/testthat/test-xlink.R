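make_xl_file <- function(rows, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  readr::write_tsv(rows, f)
  f
}

test_that("crosslink tables read with mandatory column checking", {
  tbl <- tibble::tibble(protein1 = c("S1", "S1", "S2"),
                        res1 = c(5L, 8L, 3L),
                        protein2 = c("S2", "S1", "S2"),
                        res2 = c(7L, 30L, 9L),
                        score = c(300, 260, 210))
  xl <- read_crosslinks(make_xl_file(tbl))
  expect_equal(nrow(xl), 3)
  expect_type(xl$res1, "integer")
  expect_error(read_crosslinks(make_xl_file(tbl[, -5])), "score")
  bad <- tbl
  bad$res1 <- as.character(bad$res1)
  bad$res1[2] <- "abc"
  expect_error(read_crosslinks(make_xl_file(bad)), "row 2")
})

test_that("column renaming and CSV dialect work", {
  tbl <- tibble::tibble(ProteinA = "S1", ResidueA = 5L, ProteinB = "S2",
                        ResidueB = 7L, AggregateScore = 300)
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tbl, f)
  xl <- read_crosslinks(f, cols = c(protein1 = "ProteinA",
                                    res1 = "ResidueA",
                                    protein2 = "ProteinB",
                                    res2 = "ResidueB",
                                    score = "AggregateScore"))
  expect_equal(xl$score, 300)
})

test_that("generator tables round-trip through the reader", {
  b <- make_bundle(2, 40)
  gen <- make_crosslinks(b, n_satisfied = 20, n_violated = 5, seed = 3)
  xl <- read_crosslinks(make_xl_file(gen$table))
  expect_equal(nrow(xl), nrow(gen$table))
  expect_equal(sort(xl$score), sort(gen$table$score), tolerance = 1e-12)
  expect_equal(xl[c("protein1", "res1", "protein2", "res2")],
               gen$table[c("protein1", "res1", "protein2", "res2")])
})

test_that("deduplication keeps the best-scoring copy of each pair", {
  tbl <- tibble::tibble(
    protein1 = c("S1", "S2"), res1 = c(5L, 7L),
    protein2 = c("S2", "S1"), res2 = c(7L, 5L),
    score = c(300, 280))              # same unordered pair, reversed order
  out <- dedup_and_filter(tbl, score_min = 0)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 300)
})

test_that("the score filter is strictly greater-than", {
  tbl <- tibble::tibble(protein1 = "S1", res1 = c(1L, 2L, 3L),
                        protein2 = "S2", res2 = c(1L, 2L, 3L),
                        score = c(251, 250, 249))
  out <- dedup_and_filter(tbl, score_min = 250)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 251)
})

test_that("dedup ties keep the first copy in input order and are idempotent", {
  tbl <- tibble::tibble(protein1 = "S1", res1 = c(5L, 5L),
                        protein2 = "S2", res2 = c(7L, 7L),
                        score = c(300, 300), replicate = c("r1", "r2"))
  out <- dedup_and_filter(tbl, score_min = 0)
  expect_equal(out$replicate, "r1")
  expect_identical(dedup_and_filter(out, score_min = 0), out)
  # output is score-sorted and all above the threshold
  gen <- make_crosslinks(make_bundle(2, 40), 20, 5, n_duplicates = 8,
                         seed = 2)
  f <- dedup_and_filter(gen$table, score_min = 250)
  expect_true(all(diff(f$score) <= 0))
  expect_true(all(f$score > 250))
  expect_lte(nrow(f), nrow(gen$table))
})

test_that("injected duplicates collapse back to the unique pair count", {
  b <- make_bundle(2, 40)
  gen <- make_crosslinks(b, 15, 5, n_duplicates = 5, seed = 7)
  expect_equal(nrow(gen$table), 25)
  out <- dedup_and_filter(gen$table, score_min = 0)
  expect_equal(nrow(out), 20)
  expect_equal(sort(augminr:::xl_pair_key(out$protein1, out$res1,
                                          out$protein2, out$res2)),
               sort(gen$truth$key))
})

test_that("mapped distances are exact on constructed coordinates", {
  s <- atom_tbl(tibble::tibble(
    chain = c("S1", "S2"), resno = c(1L, 1L), elety = "CA",
    x = c(0, 10), y = 0, z = 0))
  xl <- tibble::tibble(protein1 = "S1", res1 = 1L,
                       protein2 = "S2", res2 = 1L, score = 300)
  m <- map_crosslinks(xl, s)
  expect_equal(m$distance, 10)
  expect_equal(m$type, "inter")
  # symmetric under endpoint swap
  xl_sw <- xl[, c(3, 4, 1, 2, 5)]
  names(xl_sw) <- names(xl)
  expect_equal(map_crosslinks(xl_sw, s)$distance, 10)
})

test_that("unmapped endpoints are flagged, not dropped", {
  s <- make_bundle(2, 20)
  xl <- tibble::tibble(protein1 = c("S1", "S1"), res1 = c(5L, 99L),
                       protein2 = "S2", res2 = c(5L, 5L),
                       score = c(300, 300))
  m <- map_crosslinks(xl, s)
  expect_equal(m$mapped, c(TRUE, FALSE))
  v <- validate_crosslinks(m)
  expect_equal(v$n_unmapped, 1)
  expect_equal(v$n_total, 2)
  expect_error(map_crosslinks(
    tibble::tibble(protein1 = "HAUS9", res1 = 1L, protein2 = "S1",
                   res2 = 1L, score = 1), s), "HAUS9")
})

test_that("a subunit mapped to several chains takes the minimum distance", {
  s <- atom_tbl(tibble::tibble(
    chain = c("A", "B", "C"), resno = 1L, elety = "CA",
    x = c(0, 5, 50), y = 0, z = 0))
  cm <- chain_map(P1 = "A", P2 = c("B", "C"))
  xl <- tibble::tibble(protein1 = "P1", res1 = 1L, protein2 = "P2",
                       res2 = 1L, score = 1)
  expect_equal(map_crosslinks(xl, s, cm)$distance, 5)
})

test_that("synthetic link distances match the generator ground truth", {
  b <- make_bundle(4, 50)
  gen <- make_crosslinks(b, 40, 10, seed = 11)
  m <- map_crosslinks(gen$table, b)
  key <- augminr:::xl_pair_key(m$protein1, m$res1, m$protein2, m$res2)
  expect_equal(m$distance, gen$truth$distance[match(key, gen$truth$key)],
               tolerance = 1e-6)
})

test_that("validation counts and percentages are conserved and exact", {
  b <- make_bundle(4, 50)
  gen <- make_crosslinks(b, 9, 1, seed = 5)
  v <- validate_crosslinks(map_crosslinks(gen$table, b))
  expect_equal(v$n_satisfied + v$n_violated + v$n_unmapped, v$n_total)
  expect_equal(v$percent_satisfied, 90)
  # all-zero distances: 100%
  s0 <- atom_tbl(tibble::tibble(chain = c("S1", "S2"), resno = 1L,
                                elety = "CA", x = 0, y = 0, z = 0))
  xl0 <- tibble::tibble(protein1 = "S1", res1 = 1L, protein2 = "S2",
                        res2 = 1L, score = 1)
  expect_equal(validate_crosslinks(map_crosslinks(xl0, s0))$percent_satisfied,
               100)
})

test_that("satisfaction is monotonically non-decreasing in the threshold", {
  b <- make_bundle(4, 50)
  gen <- make_crosslinks(b, 30, 30, seed = 6)
  m <- map_crosslinks(gen$table, b)
  pct <- vapply(c(10, 20, 30, 40, 60, 90),
                function(d) validate_crosslinks(m, d_max = d)$percent_satisfied,
                numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("the satisfied threshold is inclusive", {
  s <- atom_tbl(tibble::tibble(chain = c("S1", "S2"), resno = 1L,
                               elety = "CA", x = c(0, 30), y = 0, z = 0))
  xl <- tibble::tibble(protein1 = "S1", res1 = 1L, protein2 = "S2",
                       res2 = 1L, score = 1)
  v <- validate_crosslinks(map_crosslinks(xl, s), d_max = 30)
  expect_equal(v$n_satisfied, 1)
})

test_that("an empty mapped set reports an undefined percentage, not an error", {
  s <- make_bundle(2, 10)
  xl <- tibble::tibble(protein1 = "S1", res1 = 99L, protein2 = "S2",
                       res2 = 99L, score = 1)
  v <- validate_crosslinks(map_crosslinks(xl, s))
  expect_true(is.na(v$percent_satisfied))
  expect_equal(v$n_unmapped, 1)
})

test_that("score export divides by the normalisation factor", {
  b <- make_bundle(2, 30)
  gen <- make_crosslinks(b, 5, 0, seed = 8)
  v <- validate_crosslinks(map_crosslinks(gen$table, b),
                           score_norm_factor = 10)
  expect_equal(v$export$norm_score, gen$table$score / 10)
})

test_that("pair count tables conserve totals and recover planted counts", {
  s <- make_bundle(3, 30)
  xl <- tibble::tibble(
    protein1 = c("S1", "S1", "S2", "S3"), res1 = c(1L, 5L, 3L, 2L),
    protein2 = c("S1", "S2", "S1", "S3"), res2 = c(9L, 8L, 7L, 6L),
    score = 300)
  v <- validate_crosslinks(map_crosslinks(xl, s))
  pc <- summarize_pairs(v)
  expect_equal(sum(pc$n), v$n_total)
  expect_equal(pc$n[pc$sub_a == "S1" & pc$sub_b == "S1"], 1)
  expect_equal(pc$n[pc$sub_a == "S1" & pc$sub_b == "S2"], 2)
  expect_equal(pc$n[pc$sub_a == "S3" & pc$sub_b == "S3"], 1)
})

test_that("violated links planted on flexible residues give observed 1", {
  # deviation grows along the chain; the flexible quantile marks the
  # tail, where the violated links are planted
  prof <- tibble::tibble(chain = rep("S1", 40), resno = 1:40,
                         deviation = seq(0.1, 8, length.out = 40))
  class(prof) <- c("flex_profile", class(prof))
  links <- tibble::tibble(
    protein1 = "S1", res1 = c(1L, 2L, 3L, 35L, 38L),
    protein2 = "S1", res2 = c(10L, 12L, 14L, 20L, 22L),
    score = 300, distance = c(5, 6, 7, 50, 60),
    mapped = TRUE, type = "intra")
  v <- validate_crosslinks(links)
  out <- flexibility_association(v, prof, n_perm = 200, seed = 1)
  expect_equal(out$observed, 1)
  # observed equals a direct recount
  thr <- quantile(prof$deviation, 0.8)
  flex_res <- prof$resno[prof$deviation > thr]
  vio <- v$links[v$links$status == "violated", ]
  expect_equal(out$observed,
               mean(vio$res1 %in% flex_res | vio$res2 %in% flex_res))
})

test_that("random labels give a non-significant association", {
  set.seed(1)
  prof <- tibble::tibble(chain = "S1", resno = 1:100,
                         deviation = runif(100))
  class(prof) <- c("flex_profile", class(prof))
  links <- tibble::tibble(
    protein1 = "S1", res1 = sample(1:100, 60, TRUE),
    protein2 = "S1", res2 = sample(1:100, 60, TRUE),
    score = 300,
    distance = sample(c(10, 50), 60, TRUE),   # random satisfied/violated
    mapped = TRUE, type = "intra")
  v <- validate_crosslinks(links)
  out <- flexibility_association(v, prof, n_perm = 999, seed = 1)
  expect_gt(out$p_value, 0.05)
})

test_that("zero violated links report an undefined statistic", {
  prof <- tibble::tibble(chain = "S1", resno = 1:10,
                         deviation = seq(0, 2, length.out = 10))
  class(prof) <- c("flex_profile", class(prof))
  links <- tibble::tibble(protein1 = "S1", res1 = 1L, protein2 = "S1",
                          res2 = 5L, score = 300, distance = 8,
                          mapped = TRUE, type = "intra")
  v <- validate_crosslinks(links)
  expect_message(out <- flexibility_association(v, prof, n_perm = 100),
                 "undefined")
  expect_true(is.na(out$observed))
})
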