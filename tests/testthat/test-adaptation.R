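test_that("the default measure matrix holds the expert binary weights", {
  mm <- load_measure_matrix()
  expect_equal(length(mm$measures), 10L)
  expect_equal(mm$lcz_columns, c(1L, 2L, 3L, 4L, 8L, 10L))
  expect_true(all(mm$weights %in% c(0, 1)))
  w <- mm$weights
  expect_equal(w["Use Reflective Building Materials", "4"], 1)
  expect_equal(w["Promote Sustainable Urban Forms", "1"], 0)
  expect_equal(unname(w["Optimize Urban Openness", ]), c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(w["Restrict Building Height", ]), c(1, 0, 0, 1, 0, 0))
  expect_equal(unname(w["Raise Pervious Surface Fraction Ratio", ]),
               c(1, 1, 1, 0, 1, 0))
  expect_equal(unname(w["Reduce Environmental Pollution", ]),
               c(1, 0, 0, 0, 1, 1))
  expect_equal(unname(w["Control Heat Emissions from Factories", ]),
               c(1, 0, 0, 0, 1, 1))
  expect_equal(unname(w["Promote Sustainable Urban Forms", ]),
               c(0, 0, 0, 0, 1, 1))
  universal <- c("Use Reflective Building Materials",
                 "Increase Green Space and Vegetation Cover",
                 "Increase Water Bodies")
  expect_true(all(w[universal, ] == 1))
  expect_equal(unname(w["Regulate Densification", ]), c(1, 1, 1, 0, 0, 0))
})

test_that("a matrix override is validated strictly", {
  td <- withr::local_tempdir()
  f <- file.path(td, "mm.csv")
  df <- data.frame(measure = c("A", "B"), LCZ1 = c(1, 0), LCZ2 = c(0, 1),
                   LCZ3 = 0, LCZ4 = 0, LCZ8 = 1, LCZ10 = c(1, 1))
  write.csv(df, f, row.names = FALSE)
  mm <- load_measure_matrix(f)
  expect_equal(mm$measures, c("A", "B"))
  expect_equal(mm$weights["A", "10"], 1)
  df$LCZ2[1] <- 2
  write.csv(df, f, row.names = FALSE)
  expect_error(load_measure_matrix(f), "non-binary")
  names(df)[3] <- "LCZ5"
  df$LCZ5[1] <- 0
  write.csv(df, f, row.names = FALSE)
  expect_error(load_measure_matrix(f), "header")
})

test_that("pure-LCZ-2 and mixed cities score as the weights dictate", {
  s2 <- setNames(numeric(17), as.character(1:17)); s2["2"] <- 1
  sc <- score_city(s2)
  expect_equal(sc[["Optimize Urban Openness"]], 1)
  expect_equal(sc[["Promote Sustainable Urban Forms"]], 0)
  expect_equal(sc[["Use Reflective Building Materials"]], 1)
  expect_equal(sc[["Increase Green Space and Vegetation Cover"]], 1)
  expect_equal(sc[["Increase Water Bodies"]], 1)
  mix <- setNames(numeric(17), as.character(1:17))
  mix[c("2", "14")] <- 0.5   # half compact mid-rise, half low plants
  scm <- score_city(mix)
  expect_equal(scm[["Use Reflective Building Materials"]], 0.5)
  # an all-natural city scores zero on every measure
  nat <- setNames(numeric(17), as.character(1:17))
  nat[as.character(11:17)] <- 1 / 7
  expect_true(all(score_city(nat) == 0))
})

test_that("scores equal a triple-loop oracle and stay within bounds", {
  mm <- load_measure_matrix()
  codes <- as.character(1:17)
  target <- as.character(mm$lcz_columns)
  set.seed(60)
  for (i in 1:200) {
    raw <- rgamma(17, 0.8)
    shares <- setNames(raw / sum(raw), codes)
    got <- score_city(shares, mm)
    # independent summation: loop measures x lcz columns explicitly
    want <- setNames(numeric(length(mm$measures)), mm$measures)
    for (m in mm$measures)
      for (cl in codes) {
        wgt <- if (cl %in% target) mm$weights[m, cl] else 0
        want[m] <- want[m] + shares[[cl]] * wgt
      }
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("moving share mass to a targeted LCZ never lowers the score", {
  mm <- load_measure_matrix()
  codes <- as.character(1:17)
  set.seed(61)
  for (i in 1:200) {
    raw <- rgamma(17, 0.8)
    shares <- setNames(raw / sum(raw), codes)
    m <- sample(mm$measures, 1)
    on <- as.character(mm$lcz_columns[mm$weights[m, ] == 1])
    off <- setdiff(codes, as.character(mm$lcz_columns[mm$weights[m, ] == 1]))
    if (!length(on) || !length(off)) next
    from <- sample(off, 1); to <- sample(on, 1)
    eps <- runif(1, 0, shares[[from]])
    moved <- shares
    moved[[from]] <- moved[[from]] - eps
    moved[[to]] <- moved[[to]] + eps
    expect_gte(score_city(moved, mm)[[m]], score_city(shares, mm)[[m]])
  }
})

test_that("continental aggregation sums and averages correctly", {
  tab <- data.frame(city_id = c("a", "b", "c"),
                    continent = c("Asia", "Asia", "Africa"),
                    exceeder = c(TRUE, TRUE, FALSE),
                    "Increase Water Bodies" = c(0.2, 0.4, 0.9),
                    check.names = FALSE)
  expect_warning(s <- aggregate_scores(tab, "sum"), "Africa")
  expect_equal(s$`Increase Water Bodies`, 0.6)
  m <- suppressWarnings(aggregate_scores(tab, "mean"))
  expect_equal(m$`Increase Water Bodies`, 0.3)
  one <- aggregate_scores(tab[2, ], "sum", exceeders_only = FALSE)
  expect_equal(one$`Increase Water Bodies`,
               suppressWarnings(
                 aggregate_scores(tab[2, ], "mean",
                                  exceeders_only = FALSE))$`Increase Water Bodies`)
  set.seed(62)
  big <- data.frame(city_id = paste0("c", 1:50),
                    continent = sample(c("Asia", "Africa", "Europe"), 50,
                                       TRUE),
                    exceeder = TRUE, score = runif(50))
  agg <- aggregate_scores(big, "sum")
  for (ct in unique(big$continent))
    expect_equal(agg$score[agg$continent == ct],
                 sum(big$score[big$continent == ct]))
})
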