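# Shared fixtures: tiny hand-checkable objects and brute-force oracles.

# ((A:1,B:1):3,C:4): d(A,B) = 2, d(A,C) = d(B,C) = 8
tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):3,C:4);")

# star tree with unit branches over the given tips
star_tree <- function(tips) {
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
}

# distance matrix d(AB)=2, d(AC)=4, d(BC)=6
abc_dist <- function() {
  m <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dist_matrix(m)
}

# brute-force abundance-weighted MPD by explicit pair enumeration
brute_mpd <- function(a, D) {
  p <- which(a > 0)
  num <- den <- 0
  for (i in p) for (j in p) if (i != j) {
    num <- num + a[i] * a[j] * D[i, j]
    den <- den + a[i] * a[j]
  }
  num / den
}

# brute-force abundance-weighted MNTD
brute_mntd <- function(a, D) {
  p <- which(a > 0)
  num <- den <- 0
  for (i in p) {
    num <- num + a[i] * min(D[i, setdiff(p, i)])
    den <- den + a[i]
  }
  num / den
}

# species-level Sorensen / Simpson from presence sets (independent formulas)
brute_sorensen <- function(sa, sb) {
  a <- length(intersect(sa, sb))
  b <- length(setdiff(sa, sb)); c <- length(setdiff(sb, sa))
  list(sor = (b + c) / (2 * a + b + c),
       sim = if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c)))
}

# small campaign used across io/alpha tests
demo_community <- function() {
  m <- matrix(c(3, 1, 0, 2,
                0, 2, 5, 1,
                1, 0, 2, 4), 3, 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("A", "B", "C", "D")))
  community_table(m, aridity = c(1, 3, 9), season = "wet", year = 2013,
                  position = 1:3)
}

demo_traits <- function() {
  q <- matrix(c(1.2, 0.4, NA, 2.2,
                3.0, 1.1, 0.8, 0.5,
                NA, 2.2, 1.4, 0.9), 4, 3,
              dimnames = list(c("A", "B", "C", "D"), c("t1", "t2", "t3")))
  cc <- matrix(c("x", "y", "x", "y"), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), "strategy"))
  trait_table(q, cc)
}
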