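test_that("dice handles identity, disjointness and the printed worked example", {
  expect_equal(dice(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(dice(c("A", "B"), c("C", "D")), 0.0)
  # two subnetworks of sizes 99 and 92 sharing 92 genes
  m <- sprintf("g%03d", 1:99)
  n <- sprintf("g%03d", 1:92)
  expect_equal(round(dice(m, n), 5), 0.96335)
  expect_error(dice(character(0), character(0)), "empty")
})

test_that("dice is symmetric, bounded, and 1 iff the sets are equal", {
  set.seed(77)
  pool <- sprintf("G%02d", 1:30)
  for (i in 1:25) {
    a <- sample(pool, sample(1:20, 1))
    b <- sample(pool, sample(1:20, 1))
    d <- dice(a, b)
    expect_equal(d, dice(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d == 1, setequal(a, b))
  }
})

test_that("most_similar maximizes DC with rank-based tie-breaking", {
  run <- fake_run(list(c("A", "B", "C"), c("A", "B"), c("D", "E")))
  hit <- most_similar(c("A", "B", "C"), run)
  expect_equal(hit$dc, 1)
  expect_equal(hit$rank, 1)

  run2 <- fake_run(list(c("A", "B"), c("D", "E")))
  hit2 <- most_similar(c("A", "B", "C"), run2)
  expect_setequal(hit2$module$genes, c("A", "B"))
  expect_equal(hit2$dc, 0.8)

  # tie in DC: two candidates each sharing one of two genes -> lower rank wins
  run3 <- fake_run(list(c("A", "X"), c("B", "Y")))
  hit3 <- most_similar(c("A", "B"), run3)
  expect_equal(hit3$rank, 1)
  expect_error(most_similar("A", structure(list(modules = list()),
                                           class = "search_run")), "no modules")
})

test_that("consensus_module intersects the top subnetwork with its matches", {
  netw <- fake_network(LETTERS[1:6])
  runs <- list(fake_run(list(c("A", "B", "C", "D"))),
               fake_run(list(c("A", "B", "C"))),
               fake_run(list(c("B", "C", "E"))))
  cm <- consensus_module(1, runs, netw)
  expect_setequal(cm$genes, c("B", "C"))
  expect_equal(cm$matched$run_b, c(2, 3))
  expect_lte(cm$size, min(3, 3)) # bounded by matched subnetwork sizes
  # identical tops across runs: CM = TN
  runs_id <- replicate(3, fake_run(list(c("A", "B", "C"))), simplify = FALSE)
  cm_id <- consensus_module(2, runs_id, netw)
  expect_setequal(cm_id$genes, c("A", "B", "C"))
  expect_error(consensus_module(1, runs[1], netw), ">= 2 runs")
})

test_that("an empty intersection yields an empty CM with a warning", {
  netw <- fake_network(LETTERS[1:6])
  runs <- list(fake_run(list(c("A", "B"))), fake_run(list(c("E", "F"))))
  expect_warning(cm <- consensus_module(1, runs, netw), "empty")
  expect_equal(cm$size, 0)
})

test_that("unique_modules merges identical gene sets and keeps provenance", {
  mk <- function(genes, run) {
    structure(list(genes = genes, source_run = run, Z = 1, S = 1,
                   size = length(genes)), class = "consensus_module")
  }
  cms <- list(mk(c("X"), 1), mk(c("X"), 2), mk(c("Y"), 3))
  u <- unique_modules(cms)
  expect_length(u, 2)
  expect_equal(u[[1]]$source_run, c(1, 2))
  ident <- unique_modules(replicate(10, mk(c("A", "B"), 1), simplify = FALSE))
  expect_length(ident, 1)
  distinct <- unique_modules(list(mk("A", 1), mk("B", 2)))
  expect_length(distinct, 2)
})

test_that("common_subnetwork intersects all consensus modules", {
  mk <- function(genes) structure(list(genes = genes, size = length(genes)),
                                  class = "consensus_module")
  one <- common_subnetwork(list(mk(c("A", "B"))))
  expect_setequal(one$genes, c("A", "B"))
  expect_warning(
    none <- common_subnetwork(list(mk(c("A")), mk(c("B")))), "empty")
  expect_length(none$genes, 0)
  three <- common_subnetwork(list(mk(c("A", "B", "C")), mk(c("B", "C", "D")),
                                  mk(c("B", "C"))))
  expect_setequal(three$genes, c("B", "C"))
})

test_that("pipeline-level invariants: CM within TN, common within every CM", {
  g <- generate_network(200, 2, seed = 31)
  pl <- plant_module(g, 15, seed = 31)
  net <- smooth_quiet(g, pl$scores)
  runs <- lapply(1:3, function(s) {
    suppressWarnings(search_run(net, search_params(3, 5, 40, 200), seed = s))
  })
  cons <- suppressWarnings(consensus_analysis(runs, net))
  for (cm in cons$cms) {
    tn <- runs[[cm$source_run[1]]]$top
    expect_true(all(cm$genes %in% tn$genes))
  }
  for (cm in cons$unique_cms) {
    if (cm$size > 0) {
      expect_true(all(cons$common$genes %in% cm$genes))
    }
  }
  expect_error(consensus_analysis(runs[1], net), ">= 2 runs")
})
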