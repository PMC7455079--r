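#' Default per-ancestry frequency table for the synthetic cohort
#'
#' Each element is a probability (or vector of probabilities) per ancestry
#' (AA, EA, NAA) used by [generate_metadata()]. The serology and drug
#' frequencies that the source cohort reports are reproduced directly:
#' anti-RNP 62/30/51%, anti-Sm 24/12%, corticosteroids 70/70/92%,
#' immunosuppressive use 39/39/58%, anti-dsDNA marginal 57.5%, low
#' complement marginal 40%, and the joint dsDNA-and-low-C frequencies
#' 23/29/37%. Low complement is drawn conditionally on dsDNA so that both
#' the marginals and the joint match. Frequencies not reported for the
#' cohort (NSAIDs, antimalarials, vasculitis, SSA/SSB, age > 50, disease
#' duration mix) are fixed field-plausible defaults, documented in the
#' methods vignette.
#'
#' @return named list of per-ancestry probabilities.
#' @export
default_frequencies <- function() {
  a <- function(aa, ea, naa) c(AA = aa, EA = ea, NAA = naa)
  list(
    rnp            = a(0.62, 0.30, 0.51),
    sm             = a(0.24, 0.12, 0.20),
    ssa            = a(0.35, 0.25, 0.33),
    ssb            = a(0.15, 0.10, 0.13),
    dsdna          = a(0.575, 0.575, 0.575),
    low_c          = a(0.40, 0.40, 0.40),
    dsdna_lowc     = a(0.23, 0.29, 0.37),
    corticosteroids = a(0.70, 0.70, 0.92),
    is_any         = a(0.39, 0.39, 0.58),
    antimalarials  = a(0.60, 0.60, 0.60),
    nsaids         = a(0.25, 0.25, 0.25),
    rash           = a(0.683, 0.683, 0.683),
    arthritis      = a(0.864, 0.864, 0.864),
    mucosal_ulcers = a(0.317, 0.317, 0.317),
    vasculitis     = a(0.05, 0.05, 0.05),
    alopecia       = a(0.589, 0.589, 0.589),
    age_gt50       = a(0.20, 0.20, 0.20),
    # P(aza, mtx, mmf, cyclophosphamide | any immunosuppressive)
    is_split       = c(aza = 0.35, mtx = 0.30, mmf = 0.30,
                       cyclophosphamide = 0.05),
    # P(c3 only, c4 only, both | low complement)
    lowc_split     = c(c3_only = 0.45, c4_only = 0.25, both = 0.30),
    duration       = c("<=1y" = 0.15, "1-5y" = 0.35, "5-10y" = 0.25,
                       ">10y" = 0.25)
  )
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the emulated study population: 216 AA, 1118 EA and 232
#' NAA female patients plus 17 female healthy controls.
#'
#' @param n_per_ancestry named counts for AA/EA/NAA patients.
#' @param n_hc healthy-control count (default 17).
#' @param frequencies per-ancestry probability list, see
#'   [default_frequencies()].
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_ancestry = c(AA = 216, EA = 1118, NAA = 232),
                          n_hc = 17, frequencies = default_frequencies(),
                          seed = 1L) {
  if (any(n_per_ancestry < 0) || n_hc < 0) {
    stop("configuration error: counts must be non-negative")
  }
  if (!all(c("AA", "EA", "NAA") %in% names(n_per_ancestry))) {
    stop("configuration error: n_per_ancestry needs AA, EA and NAA counts")
  }
  probs <- unlist(frequencies[setdiff(names(frequencies),
                                      c("is_split", "lowc_split", "duration"))])
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  structure(list(n_per_ancestry = n_per_ancestry, n_hc = n_hc,
                 frequencies = frequencies, seed = as.integer(seed)),
            class = "cohort_config")
}

.ancestries <- c("AA", "EA", "NAA")
.duration_levels <- c("<=1y", "1-5y", "5-10y", ">10y")
.drug_cols <- c("corticosteroids", "antimalarials", "nsaids", "aza", "mtx",
                "mmf", "cyclophosphamide")
.manifestation_cols <- c("rash", "arthritis", "mucosal_ulcers", "vasculitis",
                         "alopecia")
.autoantibody_cols <- c("dsdna", "rnp", "sm", "ssa", "ssb")

#' Generate synthetic sample metadata
#'
#' Draws one record per patient and control. Autoantibody, drug and
#' manifestation flags are Bernoulli draws at the configured per-ancestry
#' frequencies (independent across flags, except that low complement is
#' drawn conditionally on anti-dsDNA to reproduce the configured joint
#' frequency, and the four immunosuppressives are allocated one-of-four
#' given a composite immunosuppressive draw). Controls carry no disease
#' flags and SLEDAI 0. Identical seed gives an identical table.
#'
#' @param config a [cohort_config()].
#' @return tibble of sample records.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  fr <- config$frequencies
  rows <- list()
  for (anc in .ancestries) {
    n <- config$n_per_ancestry[[anc]]
    if (n == 0L) next
    p <- function(key) fr[[key]][[anc]]
    dsdna <- stats::runif(n) < p("dsdna")
    # conditional low-C keeps both marginals and the joint on target
    p_joint <- p("dsdna_lowc")
    if (p_joint > min(p("dsdna"), p("low_c"))) {
      stop("configuration error: joint dsDNA&lowC exceeds a marginal for ", anc)
    }
    p_lowc_given <- if (p("dsdna") > 0) p_joint / p("dsdna") else 0
    p_lowc_not <- if (p("dsdna") < 1) {
      (p("low_c") - p_joint) / (1 - p("dsdna"))
    } else 0
    if (p_lowc_not < 0 || p_lowc_not > 1) {
      stop("configuration error: inconsistent dsDNA / low-C frequencies for ",
           anc)
    }
    low_c <- stats::runif(n) < ifelse(dsdna, p_lowc_given, p_lowc_not)
    lowc_cat <- sample(c("c3_only", "c4_only", "both"), n, replace = TRUE,
                       prob = fr$lowc_split)
    is_any <- stats::runif(n) < p("is_any")
    is_drug <- sample(names(fr$is_split), n, replace = TRUE,
                      prob = fr$is_split)
    df <- tibble::tibble(
      sample_id = sprintf("%s_%04d", anc, seq_len(n)),
      ancestry = anc, sex = "F", is_control = FALSE,
      sledai = 6L + stats::rpois(n, 3),
      dsdna = dsdna,
      rnp = stats::runif(n) < p("rnp"),
      sm = stats::runif(n) < p("sm"),
      ssa = stats::runif(n) < p("ssa"),
      ssb = stats::runif(n) < p("ssb"),
      c3_low = low_c & lowc_cat %in% c("c3_only", "both"),
      c4_low = low_c & lowc_cat %in% c("c4_only", "both"),
      corticosteroids = stats::runif(n) < p("corticosteroids"),
      antimalarials = stats::runif(n) < p("antimalarials"),
      nsaids = stats::runif(n) < p("nsaids"),
      aza = is_any & is_drug == "aza",
      mtx = is_any & is_drug == "mtx",
      mmf = is_any & is_drug == "mmf",
      cyclophosphamide = is_any & is_drug == "cyclophosphamide",
      rash = stats::runif(n) < p("rash"),
      arthritis = stats::runif(n) < p("arthritis"),
      mucosal_ulcers = stats::runif(n) < p("mucosal_ulcers"),
      vasculitis = stats::runif(n) < p("vasculitis"),
      alopecia = stats::runif(n) < p("alopecia"),
      age_gt50 = stats::runif(n) < p("age_gt50"),
      duration_cat = sample(.duration_levels, n, replace = TRUE,
                            prob = fr$duration)
    )
    rows[[anc]] <- df
  }
  if (config$n_hc > 0L) {
    n <- config$n_hc
    hc <- tibble::tibble(
      sample_id = sprintf("HC_%04d", seq_len(n)),
      ancestry = "EA", sex = "F", is_control = TRUE, sledai = 0L,
      dsdna = FALSE, rnp = FALSE, sm = FALSE, ssa = FALSE, ssb = FALSE,
      c3_low = FALSE, c4_low = FALSE,
      corticosteroids = FALSE, antimalarials = FALSE, nsaids = FALSE,
      aza = FALSE, mtx = FALSE, mmf = FALSE, cyclophosphamide = FALSE,
      rash = FALSE, arthritis = FALSE, mucosal_ulcers = FALSE,
      vasculitis = FALSE, alopecia = FALSE,
      age_gt50 = FALSE, duration_cat = NA_character_
    )
    rows[["HC"]] <- hc
  }
  do.call(rbind, rows)
}

#' Default 34-module whole-blood collection over a synthetic gene universe
#'
#' Builds 34 named cell-type and process modules (T cell, B cell, plasma
#' cell, NK, monocyte, granulocyte, LDG, interferon, inflammasome, ... )
#' from a synthetic gene universe, with sizes drawn from 10-50 genes. The
#' five sex-linked genes (XIST, TSIX, UTY, RPS4Y1, USP9Y) are appended to
#' the universe (not to any module) so sex QC can run on generated data.
#'
#' @param n_genes universe size including filler genes (default 2000).
#' @param seed integer seed for module size draws.
#' @return a [module_collection()] whose `universe` covers all `n_genes`
#'   genes plus the sex genes.
#' @export
default_modules <- function(n_genes = 2000L, seed = 42L) {
  names34 <- c(
    "T_cell", "T_activated", "T_cytotoxic", "TCRA", "TCRB", "Treg",
    "B_cell", "Ig", "plasma_cell", "NK_cell", "pDC", "DC",
    "monocyte", "monocyte_surface", "myeloid_secreted", "granulocyte",
    "LDG", "neutrophil", "erythrocyte", "platelet",
    "cell_cycle", "IGS", "inflammasome", "IL1", "TNF",
    "antiinflammation", "unfolded_protein_response", "MHC_II",
    "SNOR_up", "SNOR_down", "anaphase", "mitochondria",
    "ROS_protection", "immune_complex")
  set.seed(seed)
  sizes <- sample(10:50, length(names34), replace = TRUE)
  if (sum(sizes) > n_genes) stop("n_genes too small for 34 modules")
  genes <- sprintf("G%05d", seq_len(n_genes))
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  mods <- stats::setNames(lapply(seq_along(names34), function(i) {
    genes[starts[i]:(starts[i] + sizes[i] - 1L)]
  }), names34)
  module_collection(mods,
                    descriptions = rep("synthetic whole-blood module",
                                       length(names34)),
                    universe = c(genes, .sex_genes))
}

#' Planted-effect table constructor
#'
#' An effect table lists (covariate, module, delta) rows: every gene of
#' `module` is shifted by `delta` log2 units in samples carrying
#' `covariate`. Covariates name a logical metadata column (e.g.
#' `"corticosteroids"`), an ancestry (`"ancestry:AA"`), or a serology group
#' (`"serology:RNP+dsDNA+"`, via [autoantibody_group()]). Effects are
#' additive across covariates.
#'
#' @param covariate,module,delta equal-length vectors.
#' @return tibble with class `effect_table`.
#' @export
effect_table <- function(covariate = character(), module = character(),
                         delta = numeric()) {
  stopifnot(length(covariate) == length(module),
            length(module) == length(delta), all(is.finite(delta)))
  out <- tibble::tibble(covariate = as.character(covariate),
                        module = as.character(module),
                        delta = as.numeric(delta))
  class(out) <- c("effect_table", class(out))
  out
}

#' Default planted effects
#'
#' Encodes the qualitative directions the emulated study reports:
#' corticosteroids raise LDG/granulocyte/monocyte/antiinflammation scores;
#' MTX and MMF lower plasma-cell and Ig scores; AZA lowers NK (and
#' T-cytotoxic/B-cell) scores; the RNP+dsDNA+ serology group raises plasma
#' cell, interferon, cell-cycle and Treg scores; AA ancestry raises
#' B/plasma-cell/Ig/Treg and NAA raises granulocyte/LDG/inflammasome/IL-1.
#' Magnitudes are artifact defaults (log2 shifts of 0.2-1.0), not
#' measurements.
#'
#' @return an [effect_table()].
#' @export
default_effect_table <- function() {
  effect_table(
    covariate = c(
      "corticosteroids", "corticosteroids", "corticosteroids", "corticosteroids",
      "mtx", "mtx", "mmf", "mmf",
      "aza", "aza", "aza",
      "serology:RNP+dsDNA+", "serology:RNP+dsDNA+", "serology:RNP+dsDNA+",
      "serology:RNP+dsDNA+",
      "ancestry:AA", "ancestry:AA", "ancestry:AA", "ancestry:AA",
      "ancestry:NAA", "ancestry:NAA", "ancestry:NAA", "ancestry:NAA"),
    module = c(
      "LDG", "granulocyte", "monocyte", "antiinflammation",
      "plasma_cell", "Ig", "plasma_cell", "Ig",
      "NK_cell", "T_cytotoxic", "B_cell",
      "plasma_cell", "IGS", "cell_cycle", "Treg",
      "plasma_cell", "B_cell", "Ig", "Treg",
      "LDG", "granulocyte", "inflammasome", "IL1"),
    delta = c(
      0.6, 0.5, 0.4, 0.4,
      -0.6, -0.5, -0.8, -0.6,
      -0.6, -0.4, -0.3,
      0.8, 1.0, 0.5, 0.4,
      0.3, 0.3, 0.3, 0.2,
      0.3, 0.3, 0.3, 0.2)
  )
}

#' Gaussian gene-level noise model
#'
#' @param baseline_mean_range interval for per-gene baseline log2 mean.
#' @param baseline_sd_range interval for per-gene SD (must be positive).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(baseline_mean_range = c(4, 12),
                        baseline_sd_range = c(0.2, 0.8)) {
  stopifnot(length(baseline_mean_range) == 2L, length(baseline_sd_range) == 2L,
            all(baseline_sd_range > 0))
  structure(list(baseline_mean_range = sort(baseline_mean_range),
                 baseline_sd_range = sort(baseline_sd_range)),
            class = "noise_model")
}

.sex_genes <- c("XIST", "TSIX", "UTY", "RPS4Y1", "USP9Y")

# which samples carry a covariate; controls never carry disease covariates
.covariate_mask <- function(metadata, covariate) {
  if (startsWith(covariate, "ancestry:")) {
    anc <- sub("^ancestry:", "", covariate)
    return(metadata$ancestry == anc & !metadata$is_control)
  }
  if (startsWith(covariate, "serology:")) {
    grp <- sub("^serology:", "", covariate)
    return(autoantibody_group(metadata) == grp & !metadata$is_control)
  }
  if (!covariate %in% names(metadata)) {
    stop("unknown covariate '", covariate, "'")
  }
  as.logical(metadata[[covariate]])
}

#' Generate module-structured log2 expression
#'
#' Each gene's value is `baseline mean + sum of planted covariate deltas on
#' modules containing the gene + Gaussian noise`. Sex-linked genes present
#' in the universe get a built-in sex effect (X genes high in females, Y
#' genes high in males, low background otherwise) so transcriptomic sex
#' inference is exercised end to end. Deterministic given `seed`.
#'
#' @param metadata tibble from [generate_metadata()].
#' @param modules a [module_collection()]; its universe (or the module gene
#'   union) defines the structured part of the gene space.
#' @param effects an [effect_table()]; every referenced module must exist.
#' @param noise a [noise_model()].
#' @param n_genes total gene count; must cover the module gene union.
#' @param seed integer seed.
#' @param per_gene_heterogeneity SD of a per-gene multiplicative jitter on
#'   planted deltas (default 0 = uniform effects).
#' @return numeric matrix, genes x samples (log2 scale).
#' @export
generate_expression <- function(metadata, modules,
                                effects = default_effect_table(),
                                noise = noise_model(),
                                n_genes = 2000L, seed = 1L,
                                per_gene_heterogeneity = 0) {
  stopifnot(inherits(modules, "module_collection"),
            inherits(noise, "noise_model"))
  unknown <- setdiff(unique(effects$module), names(modules$modules))
  if (length(unknown) > 0L) {
    stop("effect table references unknown module(s): ",
         paste(unknown, collapse = ", "))
  }
  mod_genes <- unique(unlist(modules$modules))
  universe <- modules$universe
  if (is.null(universe)) {
    n_fill <- n_genes - length(mod_genes)
    if (n_fill < 0L) stop("n_genes smaller than the module gene union")
    universe <- c(mod_genes, sprintf("N%05d", seq_len(n_fill)))
  }
  if (!all(mod_genes %in% universe)) stop("module genes missing from universe")
  set.seed(seed)
  n_g <- length(universe)
  n_s <- nrow(metadata)
  mu <- stats::runif(n_g, noise$baseline_mean_range[1L],
                     noise$baseline_mean_range[2L])
  sd_g <- stats::runif(n_g, noise$baseline_sd_range[1L],
                       noise$baseline_sd_range[2L])
  names(mu) <- names(sd_g) <- universe
  # built-in sex dimorphism for the five sex-linked genes
  sex_present <- intersect(.sex_genes, universe)
  if (length(sex_present) > 0L) mu[sex_present] <- 2
  expr <- matrix(mu, n_g, n_s) +
    matrix(stats::rnorm(n_g * n_s, sd = sd_g), n_g, n_s)
  dimnames(expr) <- list(universe, metadata$sample_id)
  if (length(sex_present) > 0L) {
    x_genes <- intersect(c("XIST", "TSIX"), sex_present)
    y_genes <- intersect(c("UTY", "RPS4Y1", "USP9Y"), sex_present)
    f <- metadata$sex == "F"
    expr[x_genes, f] <- expr[x_genes, f] + 6
    expr[y_genes, !f] <- expr[y_genes, !f] + 6
  }
  if (nrow(effects) > 0L) {
    for (i in seq_len(nrow(effects))) {
      mask <- .covariate_mask(metadata, effects$covariate[i])
      if (!any(mask)) next
      g <- modules$modules[[effects$module[i]]]
      d <- effects$delta[i]
      if (per_gene_heterogeneity > 0) {
        d <- d * (1 + stats::rnorm(length(g), sd = per_gene_heterogeneity))
        expr[g, mask] <- expr[g, mask] + d
      } else {
        expr[g, mask] <- expr[g, mask] + d
      }
    }
  }
  expr
}

#' Write the synthetic cohort to plain-text files
#'
#' Expression as TSV (gene rows, sample-id header), metadata as CSV and the
#' configuration (including the seed) as YAML; each write is logged with
#' the seed so runs are traceable.
#'
#' @param expr genes x samples matrix.
#' @param metadata sample tibble.
#' @param config the [cohort_config()] used.
#' @param dir output directory (created if needed).
#' @return named list of the written paths, invisibly.
#' @export
write_cohort <- function(expr, metadata, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                metadata = file.path(dir, "metadata.csv"),
                config = file.path(dir, "config.yaml"))
  write_expression_tsv(expr, paths$expression)
  utils::write.csv(metadata, paths$metadata, row.names = FALSE)
  yaml::write_yaml(list(n_per_ancestry = as.list(config$n_per_ancestry),
                        n_hc = config$n_hc, seed = config$seed),
                   paths$config)
  message("wrote synthetic cohort (seed ", config$seed, ") to ", dir)
  invisible(paths)
}
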