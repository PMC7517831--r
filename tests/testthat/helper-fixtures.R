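# Shared fixtures, built in code at test time.

# random point set, reproducible
rand_points <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 3), n, 3)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# arbitrary proper rotation from three angles
rotation_xyz <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  rx %*% ry %*% rotation_z(c)
}

# benzene as a Molecule: flat hexagon, kekulized bonds
benzene_molecule <- function(rot = diag(3), shift = c(0, 0, 0), id = "benzene") {
  ang <- seq(0, 5) * pi / 3
  xyz <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, `+`)
  atoms <- data.frame(element = rep("C", 6), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], charge = 0L, explicit_h = 0L)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = rep(c(1L, 2L), 3))
  structure(list(atoms = atoms, bonds = bonds, id = id), class = "Molecule")
}

# build a Molecule from explicit atoms/bonds tables
make_molecule <- function(elements, xyz, bonds, charge = 0L, id = "mol") {
  atoms <- data.frame(element = elements, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], charge = rep_len(as.integer(charge),
                                                     length(elements)),
                      explicit_h = 0L)
  mol <- structure(list(atoms = atoms, bonds = bonds, id = id), class = "Molecule")
  mol$atoms$explicit_h <- ensembleVS:::count_explicit_h(mol)
  mol
}

# binding sites with a fixed residue-key set and given CA coordinates
make_site <- function(id, ca, keys = NULL) {
  if (is.null(keys)) keys <- sprintf("A_%05d", seq_len(nrow(ca)))
  rownames(ca) <- keys
  structure(list(structure_id = id, residues = keys, ca_coords = ca,
                 all_atom_coords = ca, resolution = NA_real_),
            class = "BindingSite")
}

# random feature-frame background for selectivity scoring
random_background <- function(n = 60, seed = 1, types = c("HBA", "HBD", "HYD", "RA", "NI", "PI")) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    data.frame(type = sample(types, k, replace = TRUE),
               x = stats::runif(k, -5, 5), y = stats::runif(k, -5, 5),
               z = stats::runif(k, -5, 5), tolerance = 1.6, weight = 1)
  })
}

# a 3-5 feature pharmacophore model at given coordinates
make_model <- function(types, xyz, tolerance = 1.6, weight = 1, id = "test_model") {
  f <- data.frame(type = types, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  tolerance = rep_len(tolerance, length(types)),
                  weight = rep_len(weight, length(types)),
                  stringsAsFactors = FALSE)
  ensembleVS:::new_pharmacophore_model(f, model_id = id)
}

# classic 5-leaf distance matrix with a hand-derivable UPGMA agglomeration:
# merges (a,b)@17, (ab,e)@22, (c,d)@28, (abe,cd)@33 (cophenetic scale)
textbook_matrix <- function() {
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m["a", "b"] <- 17; m["a", "c"] <- 21; m["a", "d"] <- 31; m["a", "e"] <- 23
  m["b", "c"] <- 30; m["b", "d"] <- 34; m["b", "e"] <- 21
  m["c", "d"] <- 28; m["c", "e"] <- 39
  m["d", "e"] <- 43
  m + t(m)
}

# independent brute-force MaxMin diversity picking (recomputes all pairwise
# distances at every step), used as the oracle for diverse_select
brute_force_maxmin <- function(fp, ids, n, first) {
  dist_ij <- function(i, j) {
    un <- sum(fp[i, ] | fp[j, ])
    if (un == 0) 0 else 1 - sum(fp[i, ] & fp[j, ]) / un
  }
  picked <- first
  while (length(picked) < n) {
    cand <- setdiff(seq_len(nrow(fp)), picked)
    mind <- vapply(cand, function(c) min(vapply(picked, function(p) dist_ij(c, p),
                                                numeric(1))), numeric(1))
    best <- cand[mind == max(mind)]
    if (length(best) > 1) best <- best[order(ids[best])][1]
    picked <- c(picked, best)
  }
  picked
}

# all permutations of a vector (tiny n), for assignment oracles
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}
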