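# synthetic_fixtures: generators for every test input of the pipeline.
# These emulate the study conditions (class-separated score tables at the
# 800:16,000 scale, receptor-ligand complexes with planted interaction
# geometry, small drug-like/rule-violating libraries); they deliberately do
# not emulate docking physics or realistic protein geometry.

#' Specification of a synthetic labeled score benchmark
#'
#' @param n_active,n_decoy class sizes (defaults: the 800 / 16,000 validation
#'   set at ratio 1:20).
#' @param columns data.frame with `structure_id`, `mode`, `mu_active`,
#'   `mu_decoy`, `sigma` (kcal/mol) per score column.
#' @param missing_rate fraction of cells marked missing (failed dockings).
#' @param seed RNG seed.
#' @return a `ScoreBenchmarkSpec` list.
#' @export
score_benchmark_spec <- function(n_active = 800, n_decoy = 16000,
                                 columns = data.frame(
                                   structure_id = "S1", mode = "XP",
                                   mu_active = -9, mu_decoy = -6, sigma = 1
                                 ),
                                 missing_rate = 0, seed = 1) {
  stopifnot(all(columns$sigma > 0), missing_rate >= 0, missing_rate < 1)
  structure(
    list(n_active = n_active, n_decoy = n_decoy, columns = columns,
         missing_rate = missing_rate, seed = seed),
    class = "ScoreBenchmarkSpec"
  )
}

#' Generate a labeled synthetic score matrix
#'
#' Gaussian class-conditional scores per column (a column with
#' `(mu_decoy - mu_active) / (sigma * sqrt(2)) = d` has closed-form ranking
#' AUC `pnorm(d)` for the lower-is-better convention). Missing cells are
#' injected uniformly at the spec's rate.
#'
#' @param spec a `ScoreBenchmarkSpec`.
#' @return list with `scores` (a `ScoreMatrix`) and `labels` (named 0/1).
#' @export
make_score_benchmark <- function(spec) {
  stopifnot(inherits(spec, "ScoreBenchmarkSpec"))
  set.seed(spec$seed)
  n <- spec$n_active + spec$n_decoy
  ids <- sprintf("C%07d", seq_len(n))
  lab <- c(rep(1L, spec$n_active), rep(0L, spec$n_decoy))
  m <- matrix(NA_real_, n, nrow(spec$columns))
  for (j in seq_len(nrow(spec$columns))) {
    cj <- spec$columns[j, ]
    m[, j] <- c(stats::rnorm(spec$n_active, cj$mu_active, cj$sigma),
                stats::rnorm(spec$n_decoy, cj$mu_decoy, cj$sigma))
    if (spec$missing_rate > 0) {
      miss <- stats::runif(n) < spec$missing_rate
      m[miss, j] <- NA_real_
    }
  }
  sm <- score_matrix(ids, m, spec$columns[, c("structure_id", "mode")])
  list(scores = sm, labels = stats::setNames(lab, ids))
}

# ---- toy receptor-ligand complexes ------------------------------------------

# Ligand fragment recipes, coordinates relative to the fragment anchor.
# "expected" lists the feature types complemented when the receptor partner
# is within its threshold; polar atoms perceive as both donor and acceptor,
# so an in-range hydroxyl plants HBD and HBA together, and an aromatic ring
# plants RA and HYD together.
fragment_recipes <- function() {
  list(
    HBA = list(  # dimethyl ether: one acceptor, no donor, no HYD group
      atoms = data.frame(element = c("C", "O", "C"),
                         x = c(-1.4, 0, 1.4), y = 0, z = 0, charge = 0L),
      bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1L),
      anchor_atom = 2L, expected = "HBA", partner = "polar"
    ),
    HBD = list(  # methanol-like hydroxyl: donor and acceptor at the O
      atoms = data.frame(element = c("O", "H"),
                         x = c(0, 0.96), y = 0, z = 0, charge = 0L),
      bonds = data.frame(a1 = 1, a2 = 2, order = 1L),
      anchor_atom = 1L, expected = c("HBD", "HBA"), partner = "polar"
    ),
    HYD = list(  # ethane: one 2-carbon apolar group
      atoms = data.frame(element = c("C", "C"),
                         x = c(-0.77, 0.77), y = 0, z = 0, charge = 0L),
      bonds = data.frame(a1 = 1, a2 = 2, order = 1L),
      anchor_atom = NA, expected = "HYD", partner = "apolar3"
    ),
    RA = list(  # benzene: aromatic ring + its hydrophobic carbons
      atoms = data.frame(
        element = rep("C", 6),
        x = 1.39 * cos(seq(0, 5) * pi / 3),
        y = 1.39 * sin(seq(0, 5) * pi / 3), z = 0, charge = 0L
      ),
      bonds = data.frame(a1 = 1:6, a2 = c(2:6, 1), order = rep(c(2L, 1L), 3)),
      anchor_atom = NA, expected = c("RA", "HYD"), partner = "apolar3"
    ),
    NI = list(  # acetate: carboxylate centroid; partner kept in the ionic
      # band (> hbond threshold) so the oxygens stay uncomplemented
      atoms = data.frame(element = c("C", "C", "O", "O"),
                         x = c(-1.5, 0, 0.6, 0.6), y = c(0, 0, 1.05, -1.05),
                         z = 0, charge = c(0L, 0L, 0L, -1L)),
      bonds = data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1L, 2L, 1L)),
      anchor_atom = NA, expected = "NI", partner = "positive"
    ),
    PI = list(  # ammonium: positive center (its N-H donors stay beyond the
      # hbond threshold of the negative partner)
      atoms = data.frame(element = "N", x = 0, y = 0, z = 0, charge = 1L),
      bonds = data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)),
      anchor_atom = 1L, expected = "PI", partner = "negative"
    )
  )
}

# anchor point used for partner placement and distance bookkeeping
fragment_anchor <- function(recipe) {
  if (!is.na(recipe$anchor_atom)) {
    as.numeric(recipe$atoms[recipe$anchor_atom, c("x", "y", "z")])
  } else if (identical(recipe$expected[1], "NI")) {
    colMeans(recipe$atoms[2:4, c("x", "y", "z")])  # COO group centroid
  } else {
    heavy <- recipe$atoms$element != "H"
    colMeans(recipe$atoms[heavy, c("x", "y", "z")])
  }
}

#' Specification of a toy receptor-ligand complex
#'
#' @param features data.frame with `type` (HBA/HBD/HYD/RA/NI/PI) and
#'   `partner_dist` (Angstrom, receptor-partner offset from the feature
#'   anchor). Offsets should sit clearly on one side of the module's
#'   interaction thresholds so each feature's survival is knowable a priori.
#' @param decoy_atoms number of far-away receptor filler atoms.
#' @param seed RNG seed (decoy placement).
#' @param spacing distance between planted fragments (Angstrom).
#' @return a `ToyComplexSpec` list.
#' @export
toy_complex_spec <- function(features, decoy_atoms = 10, seed = 1, spacing = 14) {
  stopifnot(is.data.frame(features),
            all(features$type %in% names(fragment_recipes())),
            all(features$partner_dist > 0))
  structure(list(features = features, decoy_atoms = decoy_atoms, seed = seed,
                 spacing = spacing),
            class = "ToyComplexSpec")
}

#' Generate a toy receptor-ligand complex
#'
#' Emits minimal PDB (receptor) and SDF V2000 (ligand) text. Each requested
#' feature becomes a ligand fragment at its own location plus a receptor
#' partner group placed `partner_dist` away along +z; filler residues sit far
#' from every fragment. The expected receptor-complemented feature types
#' under the default thresholds are returned for auditing.
#'
#' @param spec a `ToyComplexSpec`.
#' @param thresholds interaction thresholds used to derive the expectation.
#' @return list with `receptor_pdb` (text), `ligand_sdf` (text),
#'   `expected_types` (character vector of complemented feature types).
#' @export
make_toy_complex <- function(spec, thresholds = default_interaction_thresholds()) {
  stopifnot(inherits(spec, "ToyComplexSpec"))
  set.seed(spec$seed)
  recipes <- fragment_recipes()

  lig_atoms <- list(); lig_bonds <- list(); n_at <- 0L
  rec_atoms <- list()
  expected <- character(0)
  resno <- 0L

  for (i in seq_len(nrow(spec$features))) {
    ty <- spec$features$type[i]
    d <- spec$features$partner_dist[i]
    rc <- recipes[[ty]]
    shift <- c((i - 1) * spec$spacing, 0, 0)
    at <- rc$atoms
    at$x <- at$x + shift[1]; at$y <- at$y + shift[2]; at$z <- at$z + shift[3]
    bd <- rc$bonds
    if (nrow(bd) > 0) { bd$a1 <- bd$a1 + n_at; bd$a2 <- bd$a2 + n_at }
    lig_atoms[[i]] <- at; lig_bonds[[i]] <- bd
    n_at <- n_at + nrow(at)

    anchor <- fragment_anchor(rc) + shift
    ppos <- anchor + c(0, 0, d)
    resno <- resno + 1L
    rec_atoms[[length(rec_atoms) + 1]] <- switch(
      rc$partner,
      polar = data.frame(atom = "O", res = "GLY", resno = resno,
                         x = ppos[1], y = ppos[2], z = ppos[3], elem = "O"),
      apolar3 = {
        off <- rbind(c(0, 0, d), c(0.8, 0, d), c(-0.8, 0, d))
        data.frame(atom = c("CG", "CD1", "CD2"), res = "LEU", resno = resno,
                   x = anchor[1] + off[, 1], y = anchor[2] + off[, 2],
                   z = anchor[3] + off[, 3], elem = "C")
      },
      positive = data.frame(atom = "NZ", res = "LYS", resno = resno,
                            x = ppos[1], y = ppos[2], z = ppos[3], elem = "N"),
      negative = data.frame(atom = "OD1", res = "ASP", resno = resno,
                            x = ppos[1], y = ppos[2], z = ppos[3], elem = "O")
    )
    thr <- switch(rc$partner, polar = thresholds$hbond,
                  apolar3 = thresholds$hydrophobic,
                  positive = thresholds$ionic, negative = thresholds$ionic)
    if (d <= thr) expected <- c(expected, rc$expected)
  }

  # far-away filler (decoy) receptor atoms, >= 25 A from every fragment
  if (spec$decoy_atoms > 0) {
    resno <- resno + 1L
    far <- data.frame(
      atom = "CA", res = "GLY",
      resno = resno:(resno + spec$decoy_atoms - 1L),
      x = stats::runif(spec$decoy_atoms, -50, 50),
      y = stats::runif(spec$decoy_atoms, 40, 80),
      z = stats::runif(spec$decoy_atoms, 40, 80),
      elem = "C"
    )
    rec_atoms[[length(rec_atoms) + 1]] <- far
  }
  rec <- do.call(rbind, rec_atoms)
  lig <- do.call(rbind, lig_atoms)
  bonds <- do.call(rbind, lig_bonds)

  list(
    receptor_pdb = format_pdb(rec),
    ligand_sdf = format_sdf(lig, bonds, title = "toy_ligand"),
    expected_types = expected
  )
}

format_pdb <- function(at, resolution = 1.80) {
  lines <- c(
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution),
    vapply(seq_len(nrow(at)), function(i) {
      sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              i, at$atom[i], at$res[i], at$resno[i],
              at$x[i], at$y[i], at$z[i], at$elem[i])
    }, character(1)),
    "END"
  )
  paste(lines, collapse = "\n")
}

format_sdf <- function(atoms, bonds, title = "mol") {
  chg_code <- ifelse(atoms$charge == 0, 0L, 4L - atoms$charge)
  lines <- c(
    title, "  ensembleVS          3D", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(atoms), nrow(bonds)),
    vapply(seq_len(nrow(atoms)), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d  0  0  0  0  0  0  0  0  0  0",
              atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i], 0L, chg_code[i])
    }, character(1)),
    if (nrow(bonds) > 0) {
      vapply(seq_len(nrow(bonds)), function(i) {
        sprintf("%3d%3d%3d  0  0  0  0", bonds$a1[i], bonds$a2[i], bonds$order[i])
      }, character(1))
    },
    "M  END", "$$$$"
  )
  paste(lines, collapse = "\n")
}

# ---- small molecule libraries ------------------------------------------------

# Curated SMILES. Every entry ends on a carbon atom so inert suffixes
# (methylene units, a halogen) attach as C-C / C-X bonds. Drug-like entries
# sit well inside every Lipinski/Veber limit even with the largest suffix;
# violators break at least one rule by a wide margin whatever the suffix.
druglike_base_smiles <- function() c(
  "CC(=O)Nc1ccc(O)cc1C",          # acetaminophen + tolyl methyl
  "CC(=O)Oc1ccccc1C(=O)OC",       # aspirin methyl ester
  "CCOC(=O)c1ccccc1C",            # ethyl toluate
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",   # caffeine
  "CC(C)Cc1ccc(cc1)C(C)C(=O)OC",  # ibuprofen methyl ester
  "c1ccc2c(c1)cccc2C",            # methylnaphthalene
  "CCN(CC)CCNC(=O)c1ccccc1C",     # procainamide-like
  "COc1ccc(CCN)cc1C",             # methoxyphenethylamine
  "CC1CCC(CC1)NC(=O)C",           # cyclohexyl acetamide
  "Cc1ccccc1NC(=O)CC",            # propionanilide
  "OCC1OC(O)C(O)C1C",             # small furanose-like diol
  "CN(C)c1ccc(cc1)C=CC",          # dimethylamino styrene
  "CC(=O)NCCc1ccccc1C",           # phenethyl acetamide
  "c1ccc(cc1)S(=O)(=O)NC",        # benzenesulfonamide n-methyl... ends on C (N-methyl)
  "COc1cc(ccc1O)C=CC",            # eugenol-like
  "CC(C)NCC(O)c1ccccc1C",         # propranolol-like fragment
  "Cc1ncccc1C(=O)NC",             # nicotinamide-like
  "CCC(=O)N1CCCC1C",              # prolinamide-like
  "CC(O)c1ccc(O)cc1C",            # methylphenyl ethanol
  "CN1CCN(CC1)c1ccccc1C",         # phenylpiperazine
  "CCOc1ccccc1OCC",               # catechol diether
  "CC(C)(C)c1ccc(O)cc1C",         # tert-butyl cresol
  "O=C1NC(=O)NC(=O)C1C",          # barbiturate core
  "Clc1ccc(cc1)C(=O)NCC",         # chlorobenzamide
  "CC1=CC(=O)CC(C)(C)C1"          # isophorone-like
)

violator_base_smiles <- function() c(
  "CCCCCCCCCCCCCCCCCCCC",                      # C20 alkane: logP, rotors
  "CCCCCCCCCCCCCCCCCCCCCCCC",                  # C24 alkane
  "CCCCCCCCCCCCOC(=O)CCCCCCCCCCC",             # laurate ester: rotors, logP
  "OCC(O)C(O)C(O)C(O)C(O)C(O)C(O)C(O)CC(O)C(O)C(O)C(O)C(O)C", # polyol: HBD > 5, MW ok, rotors
  "c1ccc(cc1)c1ccc(cc1)c1ccc(cc1)c1ccc(cc1)c1ccc(cc1)c1ccccc1C", # sexiphenyl: MW, logP
  "NCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCC",  # long PEG-amine: MW > 500, rotors
  "O=C(O)CCCCCCCCCCCCCCCCCCCCC(=O)OCCCCCCCCCC", # diacid ester: everything
  "OC(=O)C(N)CC(=O)NC(CO)C(=O)NC(CO)C(=O)NC(CO)C(=O)NC(CO)C(=O)NC(CO)C(O)=O.CC" # peptide-like: HBD, TPSA -- ends on C via dot component
)

#' Generate a deterministic small-molecule SMILES library
#'
#' Draws from curated drug-like and rule-violating SMILES, extended with
#' inert suffixes (methylene units and an optional halogen on the appended
#' carbon) to reach `n` unique entries. Drug-like variants stay inside every
#' Lipinski/Veber limit; violator variants always break at least one rule.
#'
#' @param n number of molecules.
#' @param seed RNG seed (assignment order).
#' @param fraction_rule_violators fraction drawn from the violating set.
#' @return data.frame with `compound_id`, `smiles`, `rule_violator`.
#' @export
make_library <- function(n, seed = 1, fraction_rule_violators = 0) {
  stopifnot(n > 0, fraction_rule_violators >= 0, fraction_rule_violators <= 1)
  n_bad <- round(n * fraction_rule_violators)
  n_good <- n - n_bad
  set.seed(seed)

  good <- expand_library(druglike_base_smiles(), n_good, max_suffix = 3,
                         halogens = c("", "F", "Cl"))
  bad <- expand_library(violator_base_smiles(), n_bad, max_suffix = Inf,
                        halogens = c("", "F", "Cl"))
  smiles <- c(good, bad)
  viol <- c(rep(FALSE, n_good), rep(TRUE, n_bad))
  ord <- sample.int(length(smiles))
  data.frame(
    compound_id = sprintf("L%06d", seq_len(n)),
    smiles = smiles[ord],
    rule_violator = viol[ord],
    stringsAsFactors = FALSE
  )
}

expand_library <- function(base, n, max_suffix, halogens) {
  if (n == 0) return(character(0))
  out <- character(0)
  k <- 0
  while (length(out) < n) {
    if (k > max_suffix) {
      stop("make_library: cannot generate ", n,
           " guaranteed drug-like molecules from the curated set (capacity ",
           length(base) * (max_suffix + 1) * length(halogens), ")")
    }
    for (h in halogens) {
      suffix <- paste0(strrep("C", k), if (nzchar(h) && k == 0) paste0("(", h, ")") else h)
      out <- unique(c(out, paste0(base, if (nzchar(suffix)) suffix else "")))
      if (length(out) >= n) break
    }
    k <- k + 1
  }
  out[seq_len(n)]
}
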