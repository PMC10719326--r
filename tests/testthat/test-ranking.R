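bundle <- function(res_u = 0, res_l = 0, hb_u = 0, hb_l = 0, mp_u = 5,
                   mp_l = 5, ratio = 90) {
  metric_bundle(residence = c(upper = res_u, lower = res_l),
                hbonds = c(upper = hb_u, lower = hb_l),
                midplane = c(upper = mp_u, lower = mp_l),
                diffusion_ratio = ratio)
}

get_row <- function(tab, drug, criterion)
  tab[tab$drug == drug & tab$criterion == criterion, ]

test_that("categorize resolves leaflets, bands and layer tags", {
  tab <- categorize(list(
    # residence 73% upper / 44% lower: both exceed 20 -> first, Both
    A = bundle(res_u = 73, res_l = 44),
    # 15% on one leaflet only -> second, tagged with that leaflet
    B = bundle(res_u = 3, res_l = 15),
    # hbonds exactly at the inclusive lower bound of the second band
    C = bundle(hb_u = 0.05)))
  expect_equal(get_row(tab, "A", "residence")$category, "first")
  expect_equal(get_row(tab, "A", "residence")$layer, "B")
  expect_equal(get_row(tab, "B", "residence")$category, "second")
  expect_equal(get_row(tab, "B", "residence")$layer, "L")
  expect_equal(get_row(tab, "C", "hbonds")$category, "second")
  expect_equal(get_row(tab, "C", "hbonds")$layer, "U")
})

test_that("a missing metric marks the criterion unavailable with a warning", {
  b <- bundle(res_u = 30, res_l = 10)
  b$diffusion_ratio <- NA_real_
  expect_warning(tab <- categorize(list(X = b)), "unavailable")
  expect_equal(get_row(tab, "X", "diffusion_ratio")$category,
               "unavailable")
  rk <- rank_drugs(tab)
  expect_equal(rk$n_first, 1)  # unavailable criteria excluded from counts
})

test_that("categories flip exactly at the configured thresholds", {
  eps <- 1e-9
  cat_of <- function(metric, value) {
    args <- switch(metric,
                   residence = list(res_u = value),
                   hbonds = list(hb_u = value),
                   midplane = list(mp_u = value),
                   diffusion_ratio = list(ratio = value))
    tab <- categorize(list(D = do.call(bundle, args)))
    get_row(tab, "D", metric)$category
  }
  # residence: first strictly above 20, second on the closed [12, 20]
  expect_equal(cat_of("residence", 20 + eps), "first")
  expect_equal(cat_of("residence", 20), "second")
  expect_equal(cat_of("residence", 12), "second")
  expect_equal(cat_of("residence", 12 - eps), "none")
  # hbonds: first strictly above 0.1, second on [0.05, 0.1]
  expect_equal(cat_of("hbonds", 0.1 + eps), "first")
  expect_equal(cat_of("hbonds", 0.1), "second")
  expect_equal(cat_of("hbonds", 0.05), "second")
  expect_equal(cat_of("hbonds", 0.05 - eps), "none")
  # midplane: first strictly below 2.6, second on [2.6, 4.16]
  expect_equal(cat_of("midplane", 2.6 - eps), "first")
  expect_equal(cat_of("midplane", 2.6), "second")
  expect_equal(cat_of("midplane", 4.16), "second")
  expect_equal(cat_of("midplane", 4.16 + eps), "none")
  # diffusivity ratio: first strictly below 25, second on [25, 35]
  expect_equal(cat_of("diffusion_ratio", 25 - eps), "first")
  expect_equal(cat_of("diffusion_ratio", 25), "second")
  expect_equal(cat_of("diffusion_ratio", 35), "second")
  expect_equal(cat_of("diffusion_ratio", 35 + eps), "none")
})

test_that("improving a metric never lowers its category (monotonicity)", {
  ord <- c(none = 0, second = 1, first = 2)
  set.seed(55)
  for (rep in 1:50) {
    res <- runif(1, 0, 40)
    tab1 <- categorize(list(M = bundle(res_u = res)))
    tab2 <- categorize(list(M = bundle(res_u = res + runif(1, 0, 15))))
    expect_gte(ord[get_row(tab2, "M", "residence")$category],
               ord[get_row(tab1, "M", "residence")$category])
    mp <- runif(1, 1, 6)
    tab3 <- categorize(list(M = bundle(mp_u = mp)))
    tab4 <- categorize(list(M = bundle(mp_u = max(mp - runif(1, 0, 2),
                                                  0.1))))
    expect_gte(ord[get_row(tab4, "M", "midplane")$category],
               ord[get_row(tab3, "M", "midplane")$category])
  }
})

test_that("ranking prefers more firsts, then seconds, then layer breadth", {
  # two all-first drugs: the one anchored to Both layers on residence wins
  all_first_B <- bundle(res_u = 80, res_l = 70, hb_u = 0.3, hb_l = 0.2,
                        mp_u = 2.0, mp_l = 2.2, ratio = 10)
  all_first_U <- bundle(res_u = 80, res_l = 5, hb_u = 0.3, hb_l = 0.2,
                        mp_u = 2.0, mp_l = 2.2, ratio = 10)
  rk <- rank_drugs(categorize(list(dU = all_first_U, dB = all_first_B)))
  expect_equal(rk$drug, c("dB", "dU"))
  expect_equal(rk$n_first, c(4, 4))

  # 2 firsts + 1 second outranks a bare 2 firsts
  two_one <- bundle(res_u = 50, hb_u = 0.3, mp_u = 3.0, ratio = 90)
  two_only <- bundle(res_u = 50, hb_u = 0.3, mp_u = 5.0, ratio = 90)
  rk2 <- rank_drugs(categorize(list(p = two_only, q = two_one)))
  expect_equal(rk2$drug, c("q", "p"))

  # all-empty categories collapse into a single annotated tie group
  rk3 <- rank_drugs(categorize(list(a = bundle(), b = bundle(),
                                    c = bundle())))
  expect_true(all(rk3$tied))
  expect_equal(unique(rk3$tie_group), 1)
  expect_equal(rk3$rank, c(1, 1, 1))
})

test_that("marks on higher-priority criteria break otherwise equal ranks", {
  # one second-category mark each: on residence vs on hydrogen bonds
  on_res <- bundle(res_u = 15)
  on_hb <- bundle(hb_u = 0.07)
  rk <- rank_drugs(categorize(list(zz = on_hb, aa = on_res)))
  expect_equal(rk$drug, c("aa", "zz"))
  expect_false(any(rk$tied))
  # same breadth (neither mark is on residence): hydrogen bonds outrank
  # mid-plane in the priority chain; names chosen adversarially
  on_hb2 <- bundle(hb_u = 0.07)
  on_mp <- bundle(mp_u = 3.0)
  rk_p <- rank_drugs(categorize(list(aaa = on_mp, zzz = on_hb2)))
  expect_equal(rk_p$drug, c("zzz", "aaa"))
  expect_false(any(rk_p$tied))
})

test_that("ranking is stable under permutation of the input rows", {
  bundles <- list(A = bundle(res_u = 30, hb_u = 0.2),
                  B = bundle(res_u = 15), C = bundle(),
                  D = bundle(res_u = 73, res_l = 44, hb_u = 0.2,
                             mp_u = 2, ratio = 20))
  rk1 <- rank_drugs(categorize(bundles))
  rk2 <- rank_drugs(categorize(rev(bundles)))
  expect_equal(rk1, rk2)
  expect_equal(rk1$drug[1], "D")
})

test_that("rank correlation handles perfect, reversed and random dipoles", {
  ranks <- c(A = 1, B = 2, C = 3, D = 4)
  expect_equal(rank_correlation(ranks, c(A = 1.1, B = 2.3, C = 3.7,
                                         D = 9)), 1)
  expect_equal(rank_correlation(ranks, c(A = 9, B = 3.7, C = 2.3,
                                         D = 1.1)), -1)
  expect_error(rank_correlation(ranks[1:2], c(A = 1, B = 2)), "3 drugs")
  # permutation null: coefficient distribution centred at zero
  set.seed(99)
  dip <- c(A = 2, B = 5, C = 7, D = 11)
  coefs <- replicate(200, {
    names(dip) <- sample(names(dip))
    rank_correlation(ranks, dip)
  })
  expect_lt(abs(mean(coefs)), 0.15)
})
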