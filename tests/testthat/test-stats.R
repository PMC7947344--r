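studyRow <- function(patient, group, image, metric, value) {
  data.frame(patient = patient, group = group, image = image,
             metric = metric, value = value)
}

test_that("aggregation averages clusters per image, then images per patient", {
  tab <- studyRow("p1", "a", "i1", "size", c(2, 4, 6))
  out <- aggregateStudy(tab, "patient")
  expect_equal(out$value, 4)
  ## two images with means 10 and 20 -> 15, unweighted by cluster count
  tab2 <- rbind(studyRow("p1", "a", "i1", "size", c(10, 10, 10, 10)),
                studyRow("p1", "a", "i2", "size", 20))
  expect_equal(aggregateStudy(tab2, "patient")$value, 15)
  byImg <- aggregateStudy(tab2, "image")
  expect_equal(sort(byImg$value), c(10, 20))
  expect_error(aggregateStudy(data.frame(x = 1)), "needs columns")
})

test_that("duplicating every image leaves patient values and p-values fixed", {
  set.seed(21)
  tab <- do.call(rbind, lapply(1:9, function(p) {
    g <- c("a", "b", "c")[(p - 1) %% 3 + 1]
    do.call(rbind, lapply(1:2, function(i)
      studyRow(paste0("p", p), g, paste0("p", p, "_i", i), "m",
               rnorm(5, mean = 10))))
  }))
  dup <- tab
  dup$image <- paste0(dup$image, "_copy")
  both <- rbind(tab, dup)
  a1 <- aggregateStudy(tab, "patient")
  a2 <- aggregateStudy(both, "patient")
  expect_equal(a1$value[order(a1$patient)], a2$value[order(a2$patient)])
  c1 <- compareGroups(a1$value, a1$group)
  c2 <- compareGroups(a2$value, a2$group)
  expect_equal(c1@p, c2@p)
})

test_that("identical groups take the ANOVA branch with p in the unit region", {
  g9 <- qnorm(ppoints(9))          # normal-looking, same in every group
  cmp <- compareGroups(rep(g9, 3), rep(c("a", "b", "c"), each = 9))
  expect_equal(cmp@test, "one-way ANOVA")
  expect_gt(cmp@p, 0.99)
  expect_equal(nrow(cmp@posthoc), 3)
})

test_that("the decision tree routes by normality and variance gates", {
  set.seed(31)
  ## lognormal groups fail Shapiro -> Kruskal-Wallis + Dunn
  v <- exp(rnorm(30, sd = 2))
  cmpKW <- compareGroups(v, rep(c("a", "b", "c"), each = 10))
  expect_equal(cmpKW@test, "Kruskal-Wallis")
  expect_match(cmpKW@posthoc$method[1], "Dunn")
  expect_match(paste(cmpKW@path, collapse = " "), "non-normal")
  ## normal but wildly unequal variance -> Welch + Games-Howell
  set.seed(33)
  vv <- c(rnorm(12, sd = 0.05), rnorm(12, sd = 0.05) , rnorm(12, sd = 30))
  cmpW <- compareGroups(vv, rep(c("a", "b", "c"), each = 12))
  if (cmpW@test == "Welch ANOVA")
    expect_match(cmpW@posthoc$method[1], "Games-Howell")
  expect_true(cmpW@test %in% c("Welch ANOVA", "Kruskal-Wallis"))
  ## small groups are refused by name
  expect_error(compareGroups(1:5, c("a", "a", "a", "b", "b")), "b")
})

test_that("the full tree keeps its nominal size under the null", {
  set.seed(41)
  g <- rep(c("a", "b", "c"), c(10, 9, 8))
  rej <- mean(replicate(400, compareGroups(rnorm(27), g)@p < 0.05))
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("group summaries report SEM over patients", {
  x <- c(1, 2, 3, 4, 10, 12, 14, 16, 20, 25, 30, 35)
  g <- rep(c("a", "b", "c"), each = 4)
  cmp <- compareGroups(x, g)
  expect_equal(cmp@summary$mean[1], mean(x[1:4]))
  expect_equal(cmp@summary$sem[2], sd(x[5:8]) / 2)
  expect_equal(cmp@summary$n, rep(4L, 3))
})

test_that("blinding round-trips exactly and leaks no label", {
  tab <- data.frame(patient = paste0("p", 1:9),
                    group = rep(c("nonAF", "paroxysmal", "persistent"), 3),
                    value = rnorm(9))
  bl <- blindGroups(tab, seed = 5)
  expect_false(any(c("nonAF", "paroxysmal", "persistent") %in%
                     bl$table$group))
  expect_false(any(grepl("nonAF|paroxysmal|persistent",
                         unlist(lapply(bl$table, as.character)))))
  restored <- unblindGroups(bl$table, bl$key)
  expect_identical(restored, tab)
  ## a wrong key is refused outright
  badKey <- bl$key; badKey$code <- rev(badKey$code)
  expect_error(unblindGroups(bl$table, badKey), "invalid blinding key")
  otherKey <- blindGroups(tab, seed = 6)$key
  expect_error(unblindGroups(bl$table, otherKey), "unknown codes")
})

test_that("different seeds assign different blinding codes", {
  tab <- data.frame(group = c("a", "b", "c"))
  codes <- vapply(1:100, function(s)
    paste(blindGroups(tab, seed = s)$key$code, collapse = "|"),
    character(1))
  expect_equal(length(unique(codes)), 100L)
  ## same seed, same codes
  expect_identical(blindGroups(tab, seed = 3)$key,
                   blindGroups(tab, seed = 3)$key)
})

test_that("reports carry group cells, p-values and provenance footers", {
  set.seed(51)
  pat <- do.call(rbind, lapply(1:9, function(p)
    data.frame(patient = paste0("p", p),
               group = c("a", "b", "c")[(p - 1) %% 3 + 1],
               metric = "size", value = rnorm(1, 10))))
  cmp <- compareGroups(pat$value, pat$group, metric = "size")
  prov <- data.frame(group = c("a", "b", "c"),
                     n_clusters = c(120L, 110L, 90L),
                     n_images = c(6L, 5L, 4L),
                     n_patients = c(3L, 3L, 3L))
  rep1 <- reportTables(pat, list(cmp), provenance = prov)
  expect_equal(rep1$csv$metric,
               c("size", "# clusters analyzed", "# images(# patients)"))
  expect_equal(rep1$csv$a[2], "120")
  expect_equal(rep1$csv$b[3], "5(3)")
  ## empty study -> header-only table
  rep0 <- reportTables(pat[0, ], list())
  expect_equal(nrow(rep0$csv), 0L)
  ## CSV round trip preserves the table
  tmp <- tempfile()
  writeReport(rep1, list(cmp), tmp)
  back <- read.csv(paste0(tmp, ".csv"), check.names = FALSE,
                   colClasses = "character")
  expect_equal(back$metric, rep1$csv$metric)
  expect_equal(back$a, as.character(rep1$csv$a))
  expect_true(file.exists(paste0(tmp, "_decisions.json")))
})
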