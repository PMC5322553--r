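make_hit <- function(org, evalue) {
  data.frame(organism_id = org, query_id = "fldA", subject_id = "scaf1",
             percent_identity = 40, alignment_length = 150, mismatches = 80,
             gap_openings = 3, q_start = 1, q_end = 150, s_start = 10,
             s_end = 160, evalue = evalue, bitscore = 120,
             stringsAsFactors = FALSE)
}

test_that("presence calling applies the e-value threshold and the complete-genome rule", {
  hits <- rbind(make_hit("org1", 1e-6), make_hit("org4", 1e-4))
  status <- c(org1 = TRUE, org2 = TRUE, org3 = FALSE, org4 = TRUE)
  tt <- call_presence(hits, status)
  got <- setNames(tt$fld_state, tt$organism_id)
  expect_identical(got[["org1"]], "present")   # hit below threshold
  expect_identical(got[["org2"]], "absent")    # no hit, complete genome
  expect_identical(got[["org3"]], "unknown")   # no hit, draft genome
  expect_identical(got[["org4"]], "absent")    # only hit above threshold
  expect_error(call_presence(make_hit("orgX", 1e-9), status),
               "missing from genome_complete")
})

test_that("presence calling never emits absent for an incomplete genome", {
  set.seed(42)
  for (rep in 1:40) {
    orgs <- paste0("g", 1:8)
    status <- setNames(sample(c(TRUE, FALSE), 8, replace = TRUE), orgs)
    hits <- do.call(rbind, lapply(sample(orgs, sample(0:8, 1)), function(o)
      make_hit(o, 10^runif(1, -12, -2))))
    tt <- if (is.null(hits)) call_presence(data.frame(), status)
          else call_presence(hits, status)
    expect_false(any(tt$fld_state == "absent" & !tt$genome_complete))
    validate_trait_table(tt)
  }
})

test_that("hit files are parsed from the 12-column tabular format", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("fldA\tctg1\t45.2\t160\t80\t3\t1\t160\t5\t164\t1e-30\t150",
               "fldA\tctg2\t30.1\t100\t65\t4\t1\t100\t9\t108\t0.002\t40"), f)
  h <- read_hits(f)
  expect_equal(nrow(h), 2)
  expect_equal(h$evalue, c(1e-30, 2e-3))
  expect_equal(h$subject_id, c("ctg1", "ctg2"))
})

sym_identity <- function(labels, vals) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 100
  m
}

test_that("greedy identity clustering matches its definition", {
  labs <- paste0("s", 1:5)
  # no-merge and full-merge limits
  lo <- sym_identity(labs, rep(10, 10))
  expect_identical(cluster_representatives(lo, 70), sort(labs))
  hi <- sym_identity(labs, rep(100, 10))
  expect_identical(cluster_representatives(hi, 70), "s1")
  # hand-built matrix vs direct replay oracle, several thresholds
  set.seed(8)
  for (rep in 1:20) {
    m <- sym_identity(labs, runif(10, 40, 100))
    for (thr in c(50, 70, 90)) {
      expect_identical(cluster_representatives(m, thr),
                       greedy_replay(m, thr, sort(labs)))
    }
  }
  bad <- sym_identity(labs, runif(10, 0, 100)); bad[1, 2] <- bad[1, 2] + 5
  expect_error(cluster_representatives(bad, 70), "symmetric")
})

test_that("representative count grows as the threshold rises", {
  set.seed(9)
  labs <- paste0("q", 1:8)
  for (rep in 1:10) {
    m <- sym_identity(labs, runif(28, 30, 100))
    sizes <- sapply(c(40, 60, 80, 95),
                    function(t) length(cluster_representatives(m, t)))
    expect_true(all(diff(sizes) >= 0))
  }
})

dist_mat <- function(labels, d) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- d
  m + t(m)
}

test_that("near-duplicate tips collapse only when pattern and distance agree", {
  tt <- trait_table(c("a", "b"), c("present", "present"),
                    iron_level = c(0L, 0L))
  d <- dist_mat(c("a", "b"), 0.004)
  expect_identical(dedup_tips(d, tt)$organism_id, "a")
  # same distance, different state: both kept
  tt2 <- trait_table(c("a", "b"), c("present", "absent"),
                     iron_level = c(0L, 0L))
  expect_identical(dedup_tips(d, tt2)$organism_id, c("a", "b"))
  # above threshold: both kept
  d2 <- dist_mat(c("a", "b"), 0.006)
  expect_identical(dedup_tips(d2, tt)$organism_id, c("a", "b"))
  # single linkage chains a-b-c even when a-c alone exceeds the threshold
  tt3 <- trait_table(c("a", "b", "c"), rep("present", 3),
                     iron_level = c(1L, 1L, 1L))
  d3 <- dist_mat(c("a", "b", "c"), c(0.004, 0.006, 0.004))  # ab, ac, bc
  expect_identical(dedup_tips(d3, tt3)$organism_id, "a")
  expect_error(dedup_tips(dist_mat(c("a", "x"), 0.1), tt), "missing")
})

test_that("dedup is idempotent and keeps the lexicographically first survivor", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    ids <- sample(paste0("org", sprintf("%02d", 1:n)))
    tt <- trait_table(ids,
                      sample(c("present", "absent"), n, replace = TRUE),
                      iron_level = sample(0:2, n, replace = TRUE))
    d <- dist_mat(ids, runif(n * (n - 1) / 2, 0, 0.01))
    once <- dedup_tips(d, tt)
    twice <- dedup_tips(d, once)
    expect_identical(once$organism_id, twice$organism_id)
    expect_identical(once$fld_state, twice$fld_state)
    expect_true(all(once$organism_id %in% ids))
  }
})

test_that("habitat frequencies tally presence over scored organisms", {
  tt <- trait_table(paste0("o", 1:12),
                    c(rep("present", 4), rep("absent", 4),
                      rep("unknown", 4)),
                    genome_complete = c(rep(TRUE, 8), rep(FALSE, 4)),
                    habitat = rep(c("lake", "ocean"), 6))
  hf <- habitat_frequency(tt)
  expect_equal(hf$n_total, c(4, 4))     # unknowns excluded
  expect_equal(hf$percent, c(50, 50))
  # empty class warning through a grouping map
  expect_warning(
    habitat_frequency(tt, c(lake = "fresh", ocean = "marine",
                            spring = "alkaline")),
    "empty habitat class")
  # zero-presence class
  t0 <- trait_table(paste0("z", 1:5), rep("absent", 5), habitat = "soil")
  expect_equal(habitat_frequency(t0)$percent, 0)
})

test_that("trait tables round-trip through TSV", {
  tt <- trait_table(c("o1", "o2"), c("present", "unknown"),
                    genome_complete = c(TRUE, FALSE),
                    habitat = c("lake", NA), iron_level = c(2L, NA))
  f <- tempfile(fileext = ".tsv")
  write_trait_table(tt, f)
  back <- read_trait_table(f)
  expect_equal(back$fld_state, tt$fld_state)
  expect_equal(back$iron_level, tt$iron_level)
})

test_that("trait table invariants are enforced", {
  expect_error(trait_table(c("a", "a"), c("present", "absent")),
               "duplicate")
  expect_error(trait_table("a", "absent", genome_complete = FALSE),
               "incomplete genome")
  expect_error(trait_table("a", "maybe"), "invalid fld_state")
  expect_error(trait_table("a", "present", iron_level = 5L), "iron_level")
})
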