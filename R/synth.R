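#' Configuration for the full-factorial rearing design
#'
#' Emulates a growth-chamber experiment crossing 2 latitudes x 2 ponds per
#' latitude x 10 maternal lines per pond x 2 rearing temperatures (20/24
#' degrees C) x 2 predator-cue levels.  Each family x treatment container
#' contributes one phenotyped larva, plus a second with probability
#' `p_second_larva` (two larvae were collected when they moulted together).
#' With the defaults the expected number of phenotyped individuals is
#' 160 * (1 + 0.7) = 272.
#'
#' @param n_latitudes,ponds_per_latitude,families_per_pond design sizes.
#' @param temperatures,predator_levels factor levels.
#' @param p_second_larva probability a container yields a second larva.
#' @param seed integer seed.
#' @return list of class `design_config`.
#' @export
design_config <- function(n_latitudes = 2, ponds_per_latitude = 2,
                          families_per_pond = 10,
                          temperatures = c(20, 24),
                          predator_levels = c("absent", "present"),
                          p_second_larva = 0.7, seed = 1L) {
  stopifnot(n_latitudes >= 1, ponds_per_latitude >= 1, families_per_pond >= 1,
            p_second_larva >= 0, p_second_larva <= 1)
  structure(list(n_latitudes = n_latitudes,
                 ponds_per_latitude = ponds_per_latitude,
                 families_per_pond = families_per_pond,
                 temperatures = temperatures,
                 predator_levels = predator_levels,
                 p_second_larva = p_second_larva,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Generate the rearing design
#'
#' One row per phenotyped larva.  Every maternal line appears in all four
#' temperature x predator combinations; each combination yields one or two
#' larvae (the second with probability `p_second_larva`).  Deterministic
#' given the seed in `cfg`.
#'
#' @param cfg a [design_config()].
#' @return a `phenotype_table` with design columns only.
#' @export
generate_design <- function(cfg = design_config()) {
  stopifnot(inherits(cfg, "design_config"))
  lat_levels <- c("high", "central")[seq_len(cfg$n_latitudes)]
  grid <- expand.grid(latitude = lat_levels,
                      pond = seq_len(cfg$ponds_per_latitude),
                      family = seq_len(cfg$families_per_pond),
                      temperature = cfg$temperatures,
                      predator = cfg$predator_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$latitude, grid$pond, grid$family,
                     grid$temperature, grid$predator), ]
  set.seed(cfg$seed)
  n_larvae <- 1L + stats::rbinom(nrow(grid), 1L, cfg$p_second_larva)
  idx <- rep(seq_len(nrow(grid)), n_larvae)
  df <- grid[idx, , drop = FALSE]
  df$pond_id <- sprintf("%s_p%d", substr(df$latitude, 1, 1), df$pond)
  df$maternal_line <- sprintf("%s_f%02d", df$pond_id, df$family)
  df$individual_id <- sprintf("ind%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  as_phenotype_table(df[c("individual_id", "pond_id", "latitude",
                          "temperature", "predator", "maternal_line")])
}

#' Trait effect model for the phenotype simulator
#'
#' Linear predictors per trait: intercept + main effects of latitude
#' (central = 1), temperature (24 = 1) and predator cue (present = 1), all
#' two-way and the three-way interaction, plus Gaussian pond and maternal-line
#' random effects and residual noise.  Mass, head width and wing pad are
#' simulated on their natural scale (mg / mm); development time on the log
#' scale with a Poisson draw (count of days).  Default magnitudes are chosen
#' to be realistic for a temperate damselfly larva reared to its prefinal
#' instar: ~5 mg wet mass, ~1 mm head width, ~2 mm wing pad, ~60 days of
#' development shortened by warming.
#'
#' @param trait one of `mass`, `head_width`, `wing_pad`, `dev_time`.
#' @param intercept,latitude,temperature,predator main effects.
#' @param lat_temp,lat_pred,temp_pred,lat_temp_pred interactions.
#' @param sd_pond,sd_family,sd_resid standard deviations (model scale).
#' @return list of class `trait_effects_1`.
#' @export
trait_effects <- function(trait, intercept, latitude = 0, temperature = 0,
                          predator = 0, lat_temp = 0, lat_pred = 0,
                          temp_pred = 0, lat_temp_pred = 0,
                          sd_pond = 0, sd_family = 0, sd_resid = 0) {
  stopifnot(sd_pond >= 0, sd_family >= 0, sd_resid >= 0)
  structure(as.list(environment()), class = "trait_effects_1")
}

#' Default trait effect models
#'
#' @return named list of [trait_effects()], one per trait.
#' @export
default_trait_effects <- function() {
  list(
    mass = trait_effects("mass", intercept = 5, latitude = 0.3,
                         temperature = 0.4, predator = -0.3, lat_temp = 0.2,
                         sd_pond = 0.15, sd_family = 0.2, sd_resid = 0.6),
    head_width = trait_effects("head_width", intercept = 1, latitude = 0.02,
                               temperature = 0.02, predator = 0.01,
                               sd_pond = 0.01, sd_family = 0.015,
                               sd_resid = 0.05),
    wing_pad = trait_effects("wing_pad", intercept = 2, latitude = 0.05,
                             temperature = 0.05, predator = -0.02,
                             sd_pond = 0.02, sd_family = 0.03,
                             sd_resid = 0.12),
    dev_time = trait_effects("dev_time", intercept = log(60),
                             latitude = -0.06, temperature = -0.12,
                             predator = -0.03, lat_temp = -0.04,
                             sd_pond = 0.02, sd_family = 0.03,
                             sd_resid = 0.05))
}

#' Null trait effect models
#'
#' Intercepts and residual noise only: no latitude/temperature/predator
#' effects and no pond or family variance, so traits are independent of the
#' environment.  Used for null-pipeline checks.
#'
#' @return named list of [trait_effects()].
#' @export
null_trait_effects <- function() {
  eff <- default_trait_effects()
  lapply(eff, function(e) {
    for (f in c("latitude", "temperature", "predator", "lat_temp", "lat_pred",
                "temp_pred", "lat_temp_pred", "sd_pond", "sd_family"))
      e[[f]] <- 0
    e
  })
}

.linpred <- function(eff, lat, temp, pred) {
  eff$intercept + eff$latitude * lat + eff$temperature * temp +
    eff$predator * pred + eff$lat_temp * lat * temp +
    eff$lat_pred * lat * pred + eff$temp_pred * temp * pred +
    eff$lat_temp_pred * lat * temp * pred
}

#' Simulate phenotypic traits on a design
#'
#' Gaussian traits are drawn on the natural scale; development time is drawn
#' Poisson with a log-link linear predictor (set
#' `suppress_dev_noise = TRUE` to replace the Poisson draw with the rounded
#' mean, useful for degenerate checks).  A negative Gaussian draw is
#' resampled up to 100 times before erroring.  Growth rates are NOT added
#' here; derive them with [derive_growth_rates()].
#'
#' @param design a design-only `phenotype_table` from [generate_design()].
#' @param effects named list from [default_trait_effects()].
#' @param seed integer seed.
#' @param suppress_dev_noise logical; drop the Poisson variation.
#' @return a `phenotype_table` with trait columns appended.
#' @export
simulate_phenotypes <- function(design, effects = default_trait_effects(),
                                seed = 1L, suppress_dev_noise = FALSE) {
  stopifnot(inherits(design, "phenotype_table"))
  if (any(.trait_cols %in% names(design)))
    stopf("design already carries trait columns")
  set.seed(seed)
  n <- nrow(design)
  lat <- as.numeric(design$latitude == "central")
  temp <- as.numeric(design$temperature == 24)
  pred <- as.numeric(design$predator == "present")
  ponds <- unique(design$pond_id); fams <- unique(design$maternal_line)
  df <- as.data.frame(design)
  for (trait in c("mass", "head_width", "wing_pad")) {
    eff <- effects[[trait]]
    re <- stats::rnorm(length(ponds), 0, eff$sd_pond)[match(design$pond_id, ponds)] +
      stats::rnorm(length(fams), 0, eff$sd_family)[match(design$maternal_line, fams)]
    mu <- .linpred(eff, lat, temp, pred) + re
    v <- mu + stats::rnorm(n, 0, eff$sd_resid)
    for (tries in seq_len(100)) {
      neg <- v <= 0
      if (!any(neg)) break
      v[neg] <- mu[neg] + stats::rnorm(sum(neg), 0, eff$sd_resid)
    }
    if (any(v <= 0))
      stopf("could not draw a positive %s after 100 resamples; effects imply negative trait values", trait)
    df[[trait]] <- v
  }
  eff <- effects$dev_time
  re <- stats::rnorm(length(ponds), 0, eff$sd_pond)[match(design$pond_id, ponds)] +
    stats::rnorm(length(fams), 0, eff$sd_family)[match(design$maternal_line, fams)]
  log_mu <- .linpred(eff, lat, temp, pred) + re +
    stats::rnorm(n, 0, eff$sd_resid)
  dev <- if (suppress_dev_noise) round(exp(log_mu))
         else stats::rpois(n, exp(log_mu))
  df$dev_time <- pmax(1L, as.integer(dev))
  as_phenotype_table(df)
}

#' Simulate phenotypes with planted canonical correlations
#'
#' Generator mode for parameter-recovery experiments.  Latent axes are
#' \eqn{s_k = \rho_k u_k + \sqrt{1-\rho_k^2}\,\epsilon_k} with
#' \eqn{u_1, u_2, u_3} the standardized temperature, latitude and
#' predator-cue codes (orthogonal in the balanced design) and
#' \eqn{\epsilon_k} independent standard normals.  Traits are then
#' deterministic monotone maps of one axis each — development time falls
#' with \eqn{s_1}, mass rises with \eqn{s_2}, log head width with
#' \eqn{s_3} — so the population canonical correlations of the processed
#' trait matrix against the environment equal `rho` exactly, and the derived
#' growth rate GRH ends up collinear with development time (|Spearman r| >
#' 0.9) and is removed by the screen, mirroring a redundant-trait situation.
#' Pond and family effects are zero in this mode (they would dilute the
#' plant).
#'
#' @param design a design-only `phenotype_table`.
#' @param rho planted canonical correlations, default `c(0.85, 0.5, 0.25)`.
#' @param seed integer seed.
#' @return a `phenotype_table` with traits; the latent axis scores are
#'   attached as attribute `"latent"` (N x 3 matrix, one column per axis).
#' @export
simulate_planted_phenotypes <- function(design, rho = c(0.85, 0.5, 0.25),
                                        seed = 1L) {
  stopifnot(inherits(design, "phenotype_table"), length(rho) == 3,
            all(rho >= 0), all(rho < 1))
  set.seed(seed)
  n <- nrow(design)
  u <- cbind(as.numeric(design$temperature == 24),
             as.numeric(design$latitude == "central"),
             as.numeric(design$predator == "present"))
  u <- scale(u)
  s <- sapply(1:3, function(k)
    rho[k] * u[, k] + sqrt(1 - rho[k]^2) * stats::rnorm(n))
  df <- as.data.frame(design)
  df$dev_time <- pmax(5L, as.integer(round(60 - 8 * s[, 1])))
  df$mass <- 5 * exp(0.22 * s[, 2])
  df$head_width <- exp(0.05 * s[, 3])
  df$wing_pad <- 2 * exp(0.1 * stats::rnorm(n))
  out <- as_phenotype_table(df)
  colnames(s) <- paste0("axis", 1:3)
  rownames(s) <- df$individual_id
  attr(out, "latent") <- s
  out
}

#' Ground-truth model for the count simulator
#'
#' Negative-binomial expression model with planted shifts: gene g in sample i
#' has mean \eqn{L_i \pi_g \exp(\gamma_g z_{i})} where \eqn{L_i} is the
#' library size (log-normal), \eqn{\pi_g} a log-normal relative abundance
#' normalized to sum 1, \eqn{z_i} the sample's latent axis score and
#' \eqn{\gamma_g} the planted natural-log fold change per unit score
#' (nonzero only for planted genes).  Dispersions are log-normal with median
#' 0.1 (typical bulk RNA-seq).
#'
#' @param n_genes number of genes, default 2000.
#' @param planted_per_axis genes planted per axis and direction (default 50
#'   up + 50 down on each axis).
#' @param n_axes number of latent axes carrying planted genes.
#' @param gamma planted |log fold change| per unit axis score.
#' @param dispersion_meanlog,dispersion_sdlog log-normal dispersion model.
#' @param lib_meanlog,lib_sdlog log-normal library-size model (median 1e6;
#'   pass `lib_meanlog = log(1e4)` for a desk-scale profile).
#' @param seed integer seed used to draw the gene-level parameters.
#' @return list of class `expression_truth` with per-gene `base_abundance`,
#'   `dispersion`, `gamma` (genes x axes) and the planted sets `planted`
#'   (data.frame gene/axis/direction).
#' @export
expression_truth <- function(n_genes = 2000, planted_per_axis = 50,
                             n_axes = 3, gamma = 1.5,
                             dispersion_meanlog = log(0.1),
                             dispersion_sdlog = 0.5,
                             lib_meanlog = log(1e6), lib_sdlog = 0.2,
                             seed = 1L) {
  stopifnot(n_genes >= 1, planted_per_axis * 2 * n_axes <= n_genes)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  ab <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  ab <- ab / sum(ab)
  phi <- stats::rlnorm(n_genes, dispersion_meanlog, dispersion_sdlog)
  G <- matrix(0, n_genes, n_axes,
              dimnames = list(genes, paste0("axis", seq_len(n_axes))))
  planted <- NULL
  if (planted_per_axis > 0) {
    pool <- sample(genes, planted_per_axis * 2 * n_axes)
    for (k in seq_len(n_axes)) {
      up <- pool[((k - 1) * 2 * planted_per_axis + 1):
                   ((k - 1) * 2 * planted_per_axis + planted_per_axis)]
      dn <- pool[((k - 1) * 2 * planted_per_axis + planted_per_axis + 1):
                   (k * 2 * planted_per_axis)]
      G[up, k] <- gamma
      G[dn, k] <- -gamma
      planted <- rbind(planted,
                       data.frame(gene = c(up, dn), axis = k,
                                  direction = rep(c("up", "down"),
                                                  each = planted_per_axis),
                                  stringsAsFactors = FALSE))
    }
  }
  structure(list(n_genes = n_genes, genes = genes, base_abundance = ab,
                 dispersion = phi, gamma = G, planted = planted,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog),
            class = "expression_truth")
}

#' Simulate a gene-level count matrix
#'
#' Draws counts from the negative-binomial model in [expression_truth()].
#' Latent axis scores `z` tie expression to the design: by default the
#' `"latent"` attribute of a table from [simulate_planted_phenotypes()] is
#' used; pass a zero matrix (or leave the design un-planted) for a null
#' simulation.
#'
#' @param design a `phenotype_table` (row order defines the sample columns).
#' @param truth an [expression_truth()].
#' @param seed integer seed.
#' @param z optional N x n_axes matrix of latent scores.
#' @return a `counts_matrix` (genes x individuals); all genes are labelled
#'   autosomal (`chrom = "A1"`).
#' @export
simulate_counts <- function(design, truth, seed = 1L, z = NULL) {
  stopifnot(inherits(design, "phenotype_table"),
            inherits(truth, "expression_truth"))
  n <- nrow(design)
  if (is.null(z)) z <- attr(design, "latent")
  if (is.null(z)) z <- matrix(0, n, ncol(truth$gamma))
  z <- as.matrix(z)
  stopifnot(nrow(z) == n)
  k <- min(ncol(z), ncol(truth$gamma))
  set.seed(seed)
  L <- stats::rlnorm(n, truth$lib_meanlog, truth$lib_sdlog)
  shift <- truth$gamma[, seq_len(k), drop = FALSE] %*%
    t(z[, seq_len(k), drop = FALSE])          # genes x samples
  mu <- (truth$base_abundance %o% L) * exp(shift)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / truth$dispersion, n)),
                   nrow = truth$n_genes,
                   dimnames = list(truth$genes, design$individual_id))
  as_counts_matrix(counts, chrom = rep("A1", truth$n_genes))
}

#' Generate a toy ontology, annotation and multi-species reference fixture
#'
#' Builds a random is_a DAG per GO namespace (a root plus terms attaching to
#' 1–2 earlier terms), an annotation mapping genes to leaf-ish terms, and a
#' reference table containing controlled transfer-rule cases: gene names
#' supported by 2, 3 or 5 species with identical GO sets, and a 3-species
#' case where one species' set differs.
#'
#' @param n_terms terms per namespace (>= 5).
#' @param n_genes genes to annotate.
#' @param seed integer seed.
#' @return list with `ontology` (an `ontology_graph`), `annotation`
#'   (gene -> terms), and `reference` (a `reference_annotation`).
#' @export
generate_ontology_fixture <- function(n_terms = 30, n_genes = 50, seed = 1L) {
  stopifnot(n_terms >= 5)
  set.seed(seed)
  ns <- c("biological_process", "cellular_component", "molecular_function")
  terms <- edges <- NULL
  for (j in seq_along(ns)) {
    ids <- sprintf("GO:%07d", (j - 1) * n_terms + seq_len(n_terms))
    terms <- rbind(terms, data.frame(
      id = ids, name = paste0(substr(ns[j], 1, 2), "_term", seq_len(n_terms)),
      namespace = ns[j], stringsAsFactors = FALSE))
    for (i in 2:n_terms) {
      n_par <- sample(1:min(2, i - 1), 1)
      pa <- sample(ids[seq_len(i - 1)], n_par)
      edges <- rbind(edges, data.frame(child = ids[i], parent = pa,
                                       stringsAsFactors = FALSE))
    }
  }
  onto <- as_ontology_graph(terms, edges)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  annotation <- lapply(genes, function(g)
    sort(sample(terms$id, sample(1:4, 1))))
  names(annotation) <- genes

  species_pool <- paste0("Insecta_sp", 1:6)
  mk_case <- function(name, n_species, divergent = FALSE) {
    go <- sort(sample(terms$id, 3))
    sp <- species_pool[seq_len(n_species)]
    rows <- data.frame(species = sp, gene_name = name,
                       function_desc = paste("function of", name),
                       stringsAsFactors = FALSE)
    rows$go_terms <- rep(list(go), n_species)
    if (divergent)
      rows$go_terms[[n_species]] <- sort(sample(setdiff(terms$id, go), 3))
    rows
  }
  reference <- rbind(mk_case("trehalase", 3),
                     mk_case("cryptochrome", 2),
                     mk_case("vitellogenin", 5),
                     mk_case("catalase-like", 3, divergent = TRUE))
  class(reference) <- c("reference_annotation", "data.frame")
  list(ontology = onto, annotation = annotation, reference = reference)
}
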