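# Cation-adduct mass arithmetic and the embedded metabolite/pathway
# reference tables used for annotation and over-representation analysis.

# Monoisotopic masses (Da) of the elements handled by the formula parser,
# CODATA/IUPAC 2021 values. Electron mass is subtracted for +1 cations.
.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)

.ELECTRON_MASS <- 0.000548579909

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style elemental formula (e.g. `"C6H12O6"`) and returns its
#' monoisotopic mass, summed from a built-in atomic isotope-mass table.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' formula_mass("C6H12O6") # glucose, 180.0634 Da
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", f)) {
      stop("cannot parse elemental formula: '", f, "'", call. = FALSE)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    tokens <- regmatches(f, list(m))[[1]]
    mass <- 0
    for (tok in tokens) {
      el <- gsub("[0-9]", "", tok)
      nt <- gsub("[^0-9]", "", tok)
      n <- if (nzchar(nt)) as.integer(nt) else 1L
      if (!el %in% names(.ATOMIC_MASS)) {
        stop("element '", el, "' not in atomic-mass table", call. = FALSE)
      }
      mass <- mass + .ATOMIC_MASS[[el]] * n
    }
    mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Singly charged cation adduct rules
#'
#' Mass shifts for the \[M+H\]+, \[M+Na\]+ and \[M+K\]+ adducts observed in
#' nanoparticle-assisted LDI-MS of plasma. Each shift is the isotopic mass
#' of the adducted atom minus one electron mass (the ion is a +1 cation);
#' `electron_correction = FALSE` drops the electron term for comparison
#' with legacy adduct tables.
#'
#' @param electron_correction Subtract the electron mass from each shift?
#' @return A data.frame with columns `name`, `mass_shift` (Da) and `charge`.
#' @export
adduct_rules <- function(electron_correction = TRUE) {
  e <- if (electron_correction) .ELECTRON_MASS else 0
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+"),
    mass_shift = c(.ATOMIC_MASS[["H"]], .ATOMIC_MASS[["Na"]], .ATOMIC_MASS[["K"]]) - e,
    charge = 1L,
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of a metabolite adduct
#'
#' @param mass Neutral monoisotopic mass (Da), vectorised.
#' @param rule Adduct name, one of `rules$name`.
#' @param rules Adduct rule table, see [adduct_rules()].
#' @return m/z in Da (singly charged, so numerically mass + shift).
#' @examples
#' adduct_mz(formula_mass("C6H12O6"), "[M+Na]+") # 203.0526
#' @export
adduct_mz <- function(mass, rule, rules = adduct_rules()) {
  stopifnot(is.numeric(mass), all(mass >= 0))
  i <- match(rule, rules$name)
  if (anyNA(i)) {
    stop("unknown adduct rule: ", paste(rule[is.na(i)], collapse = ", "), call. = FALSE)
  }
  if (any(rules$charge[i] != 1L)) stop("only singly charged rules are supported")
  (mass + rules$mass_shift[i]) / 1
}

#' Embedded metabolite reference table
#'
#' Small plasma-metabolite reference set centred on markers reported for
#' COPD and its acute exacerbations: lactic acid, 3-hydroxybutyric acid,
#' uric acid and malondialdehyde (up in exacerbation), creatine,
#' dimethylglycine, threonine and fucose (down), plus glucose and a few
#' common plasma metabolites as annotation background. Monoisotopic masses
#' are computed from the formulas at call time, never stored as literals.
#'
#' @return data.frame with columns `name`, `abbrev`, `formula`,
#'   `monoisotopic_mass`.
#' @export
metabolite_db <- function() {
  db <- data.frame(
    name = c(
      "lactic acid", "3-hydroxybutyric acid", "uric acid", "malondialdehyde",
      "creatine", "dimethylglycine", "threonine", "fucose",
      "glucose", "glycine", "serine", "betaine", "choline",
      "pyruvic acid", "hypoxanthine", "xanthine", "acetoacetic acid",
      "alanine", "proline", "phenylalanine", "arginine", "asparagine",
      "glutamine", "histidine", "citric acid", "taurine"
    ),
    abbrev = c(
      "Laa", "Hya", "Ura", "Mal", "Cre", "Dim", "Thr", "Fuc",
      "Glc", "Gly", "Ser", "Bet", "Cho", "Pyr", "Hpx", "Xan", "Aca",
      "Ala", "Pro", "Phe", "Arg", "Asn", "Gln", "His", "Cit", "Tau"
    ),
    formula = c(
      "C3H6O3", "C4H8O3", "C5H4N4O3", "C3H4O2",
      "C4H9N3O2", "C4H9NO2", "C4H9NO3", "C6H12O5",
      "C6H12O6", "C2H5NO2", "C3H7NO3", "C5H11NO2", "C5H13NO",
      "C3H4O3", "C5H4N4O", "C5H4N4O2", "C4H6O3",
      "C3H7NO2", "C5H9NO2", "C9H11NO2", "C6H14N4O2", "C4H8N2O3",
      "C5H10N2O3", "C6H9N3O2", "C6H8O7", "C2H7NO3S"
    ),
    stringsAsFactors = FALSE
  )
  db$monoisotopic_mass <- formula_mass(db$formula)
  db
}

#' Embedded pathway membership map
#'
#' KEGG-style pathway sets over the metabolites of [metabolite_db()], for
#' testing over-representation analysis offline. User-supplied named lists
#' of metabolite-name vectors work the same way in [enrich_pathways()].
#'
#' @return Named list of character vectors of metabolite names.
#' @export
pathway_db <- function() {
  list(
    "Glycine, serine and threonine metabolism" =
      c("glycine", "serine", "threonine", "creatine", "dimethylglycine",
        "betaine", "choline"),
    "Glycolysis / Gluconeogenesis" =
      c("glucose", "lactic acid", "pyruvic acid"),
    "Pyruvate metabolism" =
      c("pyruvic acid", "lactic acid", "malondialdehyde", "acetoacetic acid"),
    "Purine metabolism" =
      c("uric acid", "hypoxanthine", "xanthine"),
    "Synthesis and degradation of ketone bodies" =
      c("3-hydroxybutyric acid", "acetoacetic acid"),
    "Fructose and mannose metabolism" =
      c("fucose", "glucose"),
    "Arginine and proline metabolism" =
      c("arginine", "proline", "creatine"),
    "Taurine and hypotaurine metabolism" =
      c("taurine", "alanine")
  )
}

#' Annotate m/z features by adduct mass matching
#'
#' For each feature m/z, reports every (metabolite, adduct) pair whose
#' theoretical adduct m/z lies within `ppm_tol` parts per million,
#' candidates ranked by absolute ppm error (best first).
#'
#' @param feature_mz Numeric vector of observed feature m/z (Da).
#' @param db Metabolite table with `name` and `monoisotopic_mass` columns.
#' @param rules Adduct rule table, see [adduct_rules()].
#' @param ppm_tol Mass-accuracy window in ppm (default 5).
#' @return data.frame with columns `feature_mz`, `metabolite`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, ordered by feature then |ppm|.
#' @export
match_features <- function(feature_mz, db = metabolite_db(),
                           rules = adduct_rules(), ppm_tol = 5) {
  stopifnot(ppm_tol > 0)
  grid <- expand.grid(im = seq_len(nrow(db)), ir = seq_len(nrow(rules)))
  theo <- db$monoisotopic_mass[grid$im] + rules$mass_shift[grid$ir]
  out <- lapply(feature_mz, function(mz) {
    ppm <- (mz - theo) / theo * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (!length(hit)) return(NULL)
    hit <- hit[order(abs(ppm[hit]))]
    data.frame(
      feature_mz = mz,
      metabolite = db$name[grid$im[hit]],
      adduct = rules$name[grid$ir[hit]],
      theoretical_mz = theo[hit],
      ppm_error = ppm[hit],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(feature_mz = numeric(), metabolite = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway over-representation
#'
#' One-sided hypergeometric tail test of each pathway's overlap with a
#' metabolite panel against a background universe, with Benjamini-Hochberg
#' adjustment across pathways.
#'
#' @param metabolites Character vector of panel metabolite names.
#' @param pathways Named list of metabolite-name vectors.
#' @param universe Background universe: either a character vector of
#'   metabolite names or a single count (the assumed number of detectable
#'   background metabolites, e.g. a few hundred for plasma). Defaults to
#'   the union of `metabolite_db()$name` and all pathway members — note
#'   that such a tiny universe makes the test very conservative.
#' @return data.frame with `pathway`, `overlap`, `pathway_size`,
#'   `panel_size`, `universe_size`, `p`, `q`, ordered by p.
#' @export
enrich_pathways <- function(metabolites, pathways = pathway_db(),
                            universe = NULL) {
  if (!length(metabolites)) {
    return(data.frame(pathway = character(), overlap = integer(),
                      pathway_size = integer(), panel_size = integer(),
                      universe_size = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(universe)) {
    universe <- union(metabolite_db()$name, unlist(pathways, use.names = FALSE))
  }
  panel <- unique(metabolites)
  if (is.numeric(universe)) {
    stopifnot(length(universe) == 1, universe >= length(panel))
    N <- as.integer(universe)
    named_universe <- NULL
  } else {
    named_universe <- unique(universe)
    if (!all(metabolites %in% named_universe)) {
      stop("panel metabolites outside the background universe: ",
           paste(setdiff(metabolites, named_universe), collapse = ", "))
    }
    N <- length(named_universe)
  }
  k <- length(panel)
  res <- lapply(names(pathways), function(pw) {
    set <- unique(pathways[[pw]])
    if (!is.null(named_universe)) set <- intersect(set, named_universe)
    K <- length(set)
    ov <- length(intersect(panel, set))
    # P(X >= ov) for X ~ Hypergeom(N, K, k)
    p <- stats::phyper(ov - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = ov, pathway_size = K,
               panel_size = k, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
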