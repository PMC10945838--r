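tpl <- molecule_template()

# place straight rods with given centres and axes into one state
rod_state <- function(centers, axes, box = 40) {
  nb <- tpl$n_beads
  s <- (seq_len(nb) - (nb + 1) / 2) * tpl$bond_r0
  pos <- do.call(rbind, lapply(seq_len(nrow(centers)), function(m) {
    u <- axes[m, ] / sqrt(sum(axes[m, ]^2))
    sweep(outer(s, u), 2, centers[m, ], `+`)
  }))
  system_state(pos, NULL, box, nb)
}

test_that("molecules farther than the cutoff form singleton clusters", {
  st <- rod_state(rbind(c(10, 10, 10), c(10, 16, 10), c(24, 24, 24)),
                  rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)))
  cs <- detect_clusters(st, contact_cutoff = 1.5)
  expect_equal(length(cs$sizes), 3)
  expect_true(all(cs$sizes == 1))
})

test_that("contact is transitive: A-B and B-C form one 3-molecule cluster", {
  st <- rod_state(rbind(c(10, 10, 10), c(10, 11.2, 10), c(10, 12.4, 10)),
                  matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE))
  cs <- detect_clusters(st, contact_cutoff = 1.5)
  expect_equal(max(cs$sizes), 3)
  expect_equal(length(unique(cs$assignment)), 1)
})

test_that("cluster partition equals the brute-force union-find oracle", {
  for (seed in c(1, 2)) {
    st <- random_system(30, 22, seed, tpl)
    cs <- detect_clusters(st, contact_cutoff = 1.5)
    want <- brute_clusters(st, 1.5)
    expect_identical(canon_partition(cs$assignment), canon_partition(want))
    expect_equal(sum(cs$sizes), 30)
  }
})

test_that("cluster partition agrees with graph components from igraph", {
  st <- random_system(25, 20, 5, tpl)
  cs <- detect_clusters(st, contact_cutoff = 1.5)
  # build the contact graph edge list by brute force
  n <- st$n_molecules; nb <- st$n_beads; L <- st$box_length
  edges <- c()
  for (mi in seq_len(n - 1)) {
    Pi <- st$positions[(mi - 1) * nb + seq_len(nb), ]
    for (mj in (mi + 1):n) {
      Pj <- st$positions[(mj - 1) * nb + seq_len(nb), ]
      hit <- FALSE
      for (a in seq_len(nb)) {
        d <- sweep(Pj, 2, Pi[a, ]); d <- d - L * round(d / L)
        if (any(rowSums(d^2) < 1.5^2)) { hit <- TRUE; break }
      }
      if (hit) edges <- c(edges, mi, mj)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  expect_identical(canon_partition(cs$assignment), canon_partition(memb))
})

test_that("clusters are detected across periodic boundaries and unwrapped coherently", {
  nb <- tpl$n_beads
  L <- 30
  s <- (seq_len(nb) - (nb + 1) / 2) * tpl$bond_r0
  # two parallel rods hugging opposite faces of the box: images touch
  p1 <- cbind(0.4, 15 + s, 15)
  p2 <- cbind(L - 0.4, 15 + s, 15)
  st <- system_state(rbind(p1, p2), NULL, L, nb)
  cs <- detect_clusters(st, contact_cutoff = 1.5)
  expect_equal(length(unique(cs$assignment)), 1)
  # after applying the shifts the two rods must be adjacent, not L apart
  unwrapped2 <- p2 + matrix(cs$shifts[2, ] - cs$shifts[1, ], nb, 3,
                            byrow = TRUE) * L
  expect_lt(abs(unwrapped2[1, 1] - p1[1, 1]), 1.5)
})

test_that("assembled mass fraction counts only clusters above the size threshold", {
  fake <- structure(list(assignment = rep(c(1, 2, 3), c(6, 2, 2)),
                         sizes = c(6, 2, 2), n_molecules = 10,
                         min_fibril_size = 5L), class = "cluster_set")
  expect_equal(assembled_mass_fraction(fake), 0.6)
  expect_equal(assembled_mass_fraction(fake, min_fibril_size = 2), 1)
  singles <- structure(list(assignment = 1:10, sizes = rep(1, 10),
                            n_molecules = 10, min_fibril_size = 5L),
                       class = "cluster_set")
  expect_equal(assembled_mass_fraction(singles, min_fibril_size = 2), 0)
  expect_error(assembled_mass_fraction(singles, min_fibril_size = 1), ">= 2")
  all_in <- structure(list(assignment = rep(1, 7), sizes = 7, n_molecules = 7,
                           min_fibril_size = 5L), class = "cluster_set")
  expect_equal(assembled_mass_fraction(all_in), 1)
})

test_that("time_to_fraction interpolates the first crossing", {
  expect_equal(time_to_fraction(c(0, 1, 2, 5, 6), c(0, 0, 0, 0, 1), 0.8), 5.8)
  # step series: 0 until t = 5 then 1; crossing converges to the step time
  tt <- seq(0, 10, by = 0.001); phi <- as.numeric(tt >= 5)
  expect_equal(time_to_fraction(tt, phi, 0.8), 5, tolerance = 1e-3)
  # exact interpolation on a linear ramp
  expect_equal(time_to_fraction(seq(0, 10, 0.5), seq(0, 10, 0.5) / 10, 0.8), 8)
  expect_true(is.na(time_to_fraction(0:10, rep(0.7, 11), 0.8)))
  expect_error(time_to_fraction(c(0, 0, 1), c(0, 1, 1), 0.8), "increasing")
  expect_error(time_to_fraction(0:2, c(0, 1, 1), 1.2), "target")
})
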