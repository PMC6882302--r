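mat <- function(v, genes, samples) {
  matrix(v, length(genes), length(samples), byrow = TRUE,
         dimnames = list(genes, samples))
}

test_that("CNR is the ratio to the reference-group mean", {
  des <- toy_design(c("r1", "r2", "c1"), reference = c("r1", "r2"))
  m <- mat(c(8, 12, 15), "gA", c("r1", "r2", "c1"))
  cnr <- compute_cnr(m, des, pseudocount = 0)
  expect_equal(cnr["gA", "c1"], 1.5)
  # reference samples are scored leave-self-in
  expect_equal(cnr["gA", "r1"], 0.8)
  expect_equal(cnr["gA", "r2"], 1.2)
})

test_that("a sample equal to the reference mean has CNR 1 and lg(CNR) 0", {
  des <- toy_design(c("r1", "r2", "c1"), reference = c("r1", "r2"))
  m <- mat(c(10, 10, 10), "gA", c("r1", "r2", "c1"))
  cnr <- compute_cnr(m, des, pseudocount = 0)
  expect_equal(unname(cnr["gA", ]), c(1, 1, 1))
  expect_equal(log10(cnr["gA", "c1"]), 0)
})

test_that("an all-zero gene with pseudocount 1 has CNR exactly 1", {
  des <- toy_design(c("r1", "r2", "c1"), reference = c("r1", "r2"))
  m <- mat(c(0, 0, 0), "gA", c("r1", "r2", "c1"))
  expect_equal(unname(compute_cnr(m, des, 1)["gA", ]), c(1, 1, 1))
})

test_that("BTIF requires both the fold band and the tolerance interval", {
  des <- toy_design(c("r1", "r2", "r3", "c1"),
                    reference = c("r1", "r2", "r3"))
  # CNR inside (0.66, 1.5): never flagged, however extreme the z-score
  m1 <- mat(c(10, 10, 10, 12), "gA", des$sample_id)
  cnr1 <- compute_cnr(m1, des, 0)
  expect_equal(cnr1["gA", "c1"], 1.2)
  b1 <- compute_btif(m1, cnr1, des, pseudocount = 0)
  expect_equal(b1["gA", "c1"], 0)

  # CNR = 2 and far outside the reference spread (sd floored at 0.1 log2
  # units): z = log2(2000/1000)/0.1 = 10 -> flagged
  m2 <- mat(c(990, 1000, 1010, 2000), "gA", des$sample_id)
  cnr2 <- compute_cnr(m2, des, 0)
  expect_equal(cnr2["gA", "c1"], 2)
  b2 <- compute_btif(m2, cnr2, des, pseudocount = 0)
  expect_equal(b2["gA", "c1"], 1)

  # CNR = 2 but the reference is so dispersed that the sample stays inside
  # the tolerance interval: z = (log2 3400 - 9.527)/2.665 = 0.827, p = 0.41
  m3 <- mat(c(100, 4000, 1000, 3400), "gA", des$sample_id)
  cnr3 <- compute_cnr(m3, des, 0)
  expect_equal(cnr3["gA", "c1"], 2)
  l2 <- log2(c(100, 4000, 1000))
  z <- (log2(3400) - mean(l2)) / sd(l2)
  expect_lt(abs(z), qnorm(0.975))
  b3 <- compute_btif(m3, cnr3, des, pseudocount = 0)
  expect_equal(b3["gA", "c1"], 0)

  expect_error(compute_btif(m1, cnr1, des, alpha = 1.2), "alpha")
})

test_that("PAS follows the role-weighted log-ratio sum", {
  genes <- c("gA", "gB")
  cnr <- mat(c(100, 100, 10, 10), genes, c("s1", "s2"))
  btif <- mat(rep(1, 4), genes, c("s1", "s2"))
  db1 <- pathway_collection(list(pathway_def("P1", "main", c(gA = 1))))
  expect_equal(unname(compute_pas(cnr, btif, db1)["P1", ]), c(2, 2))
  db2 <- pathway_collection(list(
    pathway_def("P2", "main", c(gA = 1, gB = -1))))
  cnr2 <- mat(rep(10, 4), genes, c("s1", "s2"))
  expect_equal(unname(compute_pas(cnr2, btif, db2)["P2", ]), c(0, 0))
})

test_that("PAS equals the brute-force term-by-term oracle", {
  withr::local_seed(42)
  for (rep in 1:30) {
    inst <- rand_pas_instance()
    expect_equal(compute_pas(inst$cnr, inst$btif, inst$db),
                 brute_pas(inst$cnr, inst$btif, inst$db),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pathways with no gene present are missing, not zero", {
  inst <- rand_pas_instance()
  db <- pathway_collection(c(inst$db$pathways,
                             list(pathway_def("absent", "main",
                                              c(zzz = 1)))))
  expect_message(pas <- compute_pas(inst$cnr, inst$btif, db), "skipped")
  expect_true(all(is.na(pas["absent", ])))
  expect_identical(attr(pas, "missing_pathways"), "absent")
})

test_that("all-zero flags force PAS to be exactly zero", {
  inst <- rand_pas_instance()
  zero <- inst$btif * 0
  pas <- compute_pas(inst$cnr, zero, inst$db)
  expect_true(all(pas == 0))
})

test_that("negating every ARR weight negates every PAS value exactly", {
  withr::local_seed(8)
  inst <- rand_pas_instance()
  neg <- pathway_collection(lapply(inst$db$pathways, function(p) {
    pathway_def(p$main_pathway, p$branch, -p$roles)
  }))
  expect_identical(compute_pas(inst$cnr, inst$btif, neg),
                   -compute_pas(inst$cnr, inst$btif, inst$db))
})

test_that("PAS is additive over disjoint pathway partitions", {
  withr::local_seed(9)
  inst <- rand_pas_instance(n_genes = 12)
  genes <- rownames(inst$cnr)
  part1 <- stats::setNames(sample(ARR_LEVELS, 6, TRUE), genes[1:6])
  part2 <- stats::setNames(sample(ARR_LEVELS, 6, TRUE), genes[7:12])
  db <- pathway_collection(list(
    pathway_def("part1", "main", part1),
    pathway_def("part2", "main", part2),
    pathway_def("union", "main", c(part1, part2))
  ))
  pas <- compute_pas(inst$cnr, inst$btif, db)
  expect_equal(pas["union", ], pas["part1", ] + pas["part2", ],
               tolerance = 1e-12)
})

test_that("a global rescaling of the matrix leaves CNR, BTIF, PAS unchanged at pseudocount 0", {
  withr::local_seed(10)
  des <- toy_design(sprintf("s%d", 1:6), reference = c("s1", "s2", "s3"))
  m <- matrix(rpois(120, 100) + 1, 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), des$sample_id))
  db <- pathway_collection(list(pathway_def(
    "P", "main", stats::setNames(sample(ARR_LEVELS, 20, TRUE),
                                 rownames(m)))))
  run <- function(mm) {
    cnr <- compute_cnr(mm, des, 0)
    btif <- compute_btif(mm, cnr, des, pseudocount = 0)
    list(cnr = cnr, btif = btif, pas = compute_pas(cnr, btif, db))
  }
  a <- run(m)
  b <- run(m * 7.3)
  expect_equal(a$cnr, b$cnr, tolerance = 1e-12)
  expect_identical(a$btif, b$btif)
  expect_equal(a$pas, b$pas, tolerance = 1e-12)
})

test_that("a planted activated pathway yields positive PAS in every affected sample", {
  db <- generate_pathway_db(20, c(10, 20), overlap_fraction = 0,
                            seed = 21)
  des <- design_grid(procedures = c("sham", "ALPPS"), timepoints = 4,
                     replicates = 3)
  planted <- pathway_names(db)[1:4]
  sim <- simulate_counts(db, des, truth_spec("ALPPS", 4, planted,
                                             "activated", 2),
                         seed = 22)
  prof <- pas_profile(sim$counts, sim$design, db)
  case <- des$sample_id[!des$is_reference]
  expect_true(all(prof$pas[planted, case] > 0))
})

test_that("write_pas emits the matrix and a parameter sidecar", {
  inst <- rand_pas_instance()
  pas <- compute_pas(inst$cnr, inst$btif, inst$db)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pas(pas, f, params = list(pseudocount = 1))
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[-1]), pas, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(yaml::read_yaml(paste0(f, ".yaml"))$pseudocount, 1)
})
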