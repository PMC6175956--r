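# Shared fixtures and independent brute-force oracles.

# brute-force direction enumeration over a bounding cube: all integer
# vectors whose sorted absolute components equal sorted (p, q, r)
brute_directions <- function(p, q, r) {
  m <- max(p, q, r)
  g <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  key <- apply(g, 1, function(v) paste(sort(abs(v)), collapse = ","))
  g[key == paste(sort(c(p, q, r)), collapse = ","), , drop = FALSE]
}

# brute-force exclusion shells: all nonzero offsets with squared distance
# <= the x-th smallest realizable squared lattice distance
brute_exclusion <- function(x) {
  if (x == 0) return(matrix(integer(0), ncol = 3))
  m <- x + 2
  g <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  d2 <- rowSums(g^2)
  g <- g[d2 > 0, , drop = FALSE]
  d2 <- d2[d2 > 0]
  g[d2 <= sort(unique(d2))[x], , drop = FALSE]
}

# canonical string set for comparing direction/offset matrices
vec_set <- function(m) sort(apply(m, 1, paste, collapse = ","))

# recursive R enumeration of valid walks (independent of the C++ engine);
# site validity checked by pairwise squared distances
brute_enumerate <- function(model, n_bonds, sub = NULL) {
  dirs <- model$directions
  excl_max <- model$max_excl_sq
  excluded_site <- function(s) {
    if (is.null(sub)) return(FALSE)
    switch(sub$kind,
      none = FALSE,
      plane = s[3] < 0,
      sphere_exterior = sum(s^2) < sub$radius^2,
      sphere_interior = sum(s^2) > sub$radius^2,
      cylinder_exterior = s[1]^2 + s[2]^2 < sub$radius^2)
  }
  start <- if (is.null(sub)) c(0, 0, 0) else sub$tether_site
  count <- 0L
  rec <- function(chain) {
    if (nrow(chain) == n_bonds + 1) { count <<- count + 1L; return() }
    tip <- chain[nrow(chain), ]
    for (k in seq_len(nrow(dirs))) {
      cand <- tip + dirs[k, ]
      if (excluded_site(cand)) next
      d2 <- colSums((t(chain) - cand)^2)
      if (any(d2 <= excl_max) || any(d2 == 0)) next
      rec(rbind(chain, cand))
    }
  }
  rec(matrix(start, 1))
  count
}

# desk-scale HSMC settings used throughout the tests
test_hsmc <- function(n_recon = 24) {
  hsmc_config(n_bar = 50, n_bar_prime = 20, n_recon = n_recon)
}

model_001 <- saw_model("nbr001excl0")
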