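#' Configuration for the synthetic paired tumor/blood cohort generator
#'
#' The generator emulates the structure of a host-sequencing gastric
#' cancer cohort: a set of genuinely tissue-resident species that are much
#' more prevalent in tumor tissue than in matched blood, a larger set of
#' reagent/environmental contaminants that appear at equal prevalence in
#' both materials, negative-binomial read counts given presence, and
#' clinicopathological covariates with planted effects (MSI tumors carry
#' higher microbial abundance and richness; optional per-covariate
#' log-fold effects produce compositional shifts).
#'
#' Counts given presence are drawn as `2 + NegBin(mu = nb_mean - 2,
#' size = nb_dispersion)`, so a "present" species always clears the
#' two-unambiguous-read prevalence rule used by decontamination and the
#' configured prevalence probabilities are exactly the prevalences the
#' decontamination stage observes in expectation ([expected_prevalence()]
#' is therefore an analytic oracle).
#'
#' @param n_tumor,n_blood Samples per material.
#' @param n_resident_species,n_contaminant_species Species counts for the
#'   two planted classes.
#' @param resident_tissue_prevalence,resident_blood_prevalence Presence
#'   probability of a resident species in tumor and blood samples;
#'   tissue must exceed blood.
#' @param contaminant_prevalence Presence probability of a contaminant,
#'   identical in tumor and blood.
#' @param nb_mean,nb_dispersion Negative-binomial mean (> 2) and size
#'   parameter for read counts given presence.
#' @param msi_fraction,ebv_fraction,cin_fraction Marginal frequencies of
#'   the latent MSI, EBV and CIN molecular subtypes (the remainder is
#'   genomically stable).
#' @param msi_abundance_multiplier Multiplier applied to resident tumor
#'   counts in MSI samples.
#' @param msi_richness_boost Additive increase of resident presence
#'   probability in MSI tumor samples (extra species, i.e. richness).
#' @param covariate_effects Tibble with columns `covariate`
#'   (`sex`, `pT`, `geography`, `msi_status`), `species` (a species id) and
#'   `log2fc`: the species' latent abundance (presence odds and count
#'   mean) scales by `2^log2fc` in tumor samples at the covariate's
#'   comparison level (male, pT3/4, asia, MSI). The default
#'   ([default_covariate_effects()]) plants a male-enrichment shift on
#'   eight resident species and a pT1/2-enrichment shift on eight others,
#'   emulating the compositional covariate effects seen in gastric tumor
#'   cohorts; use `NULL` for none.
#' @param mode `"wgs_like"` (whole genomes: human reads, ploidy and purity
#'   available, full depth) or `"wes_like"` (exomes: those fields missing,
#'   depth and detection reduced).
#' @param wes_prevalence_factor,wes_depth_factor Multipliers applied to
#'   all presence probabilities and to `nb_mean` in `wes_like` mode.
#' @param cohort Cohort label, `"A"` or `"B"`.
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `gc_sim_config`.
#' @export
cohort_config <- function(n_tumor = 80, n_blood = 80,
                          n_resident_species = 100,
                          n_contaminant_species = 200,
                          resident_tissue_prevalence = 0.4,
                          resident_blood_prevalence = 0.02,
                          contaminant_prevalence = 0.3,
                          nb_mean = 50, nb_dispersion = 0.8,
                          msi_fraction = 0.22, ebv_fraction = 0.09,
                          cin_fraction = 0.50,
                          msi_abundance_multiplier = 4,
                          msi_richness_boost = 0.15,
                          covariate_effects =
                            default_covariate_effects(n_resident_species),
                          mode = c("wgs_like", "wes_like"),
                          wes_prevalence_factor = 0.5,
                          wes_depth_factor = 0.25,
                          cohort = c("A", "B"),
                          seed = 1L) {
  cfg <- list(
    n_tumor = n_tumor, n_blood = n_blood,
    n_resident_species = n_resident_species,
    n_contaminant_species = n_contaminant_species,
    resident_tissue_prevalence = resident_tissue_prevalence,
    resident_blood_prevalence = resident_blood_prevalence,
    contaminant_prevalence = contaminant_prevalence,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    msi_fraction = msi_fraction, ebv_fraction = ebv_fraction,
    cin_fraction = cin_fraction,
    msi_abundance_multiplier = msi_abundance_multiplier,
    msi_richness_boost = msi_richness_boost,
    covariate_effects = covariate_effects,
    mode = match.arg(mode),
    wes_prevalence_factor = wes_prevalence_factor,
    wes_depth_factor = wes_depth_factor,
    cohort = match.arg(cohort),
    seed = as.integer(seed)
  )
  class(cfg) <- "gc_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted covariate effects
#'
#' A 1.5 log2-fold male enrichment on eight resident species and a 1.5
#' log2-fold pT1/2 enrichment (negative shift at pT3/4) on eight others,
#' placed away from the first twenty residents so that explicitly
#' configured MSI effects never overlap them. Cohorts with fewer than 40
#' resident species get no default effects.
#'
#' @param n_resident_species Number of resident species in the cohort.
#' @return A tibble with columns `covariate`, `species`, `log2fc`.
#' @export
default_covariate_effects <- function(n_resident_species) {
  if (n_resident_species < 40) return(NULL)
  tibble::tibble(
    covariate = rep(c("sex", "pT"), each = 8),
    species = sprintf("res_%03d", c(21:28, 31:38)),
    log2fc = rep(c(1.5, -1.5), each = 8)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_tumor >= 1, cfg$n_blood >= 1,
    cfg$n_resident_species >= 1, cfg$n_contaminant_species >= 1,
    cfg$nb_mean > 2, cfg$nb_dispersion > 0,
    cfg$msi_abundance_multiplier > 0, cfg$msi_richness_boost >= 0
  )
  probs <- c(cfg$resident_tissue_prevalence, cfg$resident_blood_prevalence,
             cfg$contaminant_prevalence, cfg$msi_fraction, cfg$ebv_fraction,
             cfg$cin_fraction, cfg$wes_prevalence_factor)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$resident_tissue_prevalence <= cfg$resident_blood_prevalence) {
    stop("resident tissue prevalence must exceed resident blood prevalence",
         call. = FALSE)
  }
  if (cfg$msi_fraction + cfg$ebv_fraction + cfg$cin_fraction > 1) {
    stop("subtype fractions must sum to at most 1", call. = FALSE)
  }
  invisible(cfg)
}

# Evaluate code with a private RNG state seeded from `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Species universe shared by both cohorts: ids, genus assignment (five
# species per genus) and deterministic genome sizes in the 1-10 Mb range.
synthetic_taxonomy <- function(n_resident, n_contaminant) {
  resident <- sprintf("res_%03d", seq_len(n_resident))
  contaminant <- sprintf("con_%03d", seq_len(n_contaminant))
  ids <- c(resident, contaminant)
  n <- length(ids)
  genus <- sprintf("Genus_%03d", (seq_len(n) - 1L) %/% 5L + 1L)
  # deterministic pseudo-random genome sizes: spread across 1-10 Mb
  sizes <- 1e6 + (seq_len(n) * 2654435761) %% 9e6
  tibble::tibble(
    taxon_id = ids,
    name = paste(genus, ids),
    rank = "species",
    genus_name = genus,
    genome_size_bp = as.numeric(sizes)
  )
}

#' Simulate one paired tumor/blood cohort
#'
#' Draws presence per species x sample from the class prevalences, read
#' counts given presence from the negative binomial, applies the MSI
#' abundance/richness effects and any per-covariate log-fold effects to
#' tumor samples, and generates metadata consistent with a latent
#' molecular subtype (MSI samples get somatic coding variant rates
#' >= 20/Mb, EBV samples an EBV load above 1e-3 virions per human cell,
#' CIN samples ploidy above 2.5). Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements `tumor` and `blood` (unambiguous-read
#'   `gc_abundance` matrices), `tumor_score`/`blood_score` (the same
#'   counts exposed under score semantics for downstream abundance and
#'   diversity stages), `metadata` (tibble), `taxonomy` (tibble) and
#'   `truth` (list with `resident_species`, `contaminant_species`,
#'   `subtype`, `effects`).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_local_seed(cfg$seed, {
    tax <- synthetic_taxonomy(cfg$n_resident_species, cfg$n_contaminant_species)
    resident <- tax$taxon_id[seq_len(cfg$n_resident_species)]
    contaminant <- setdiff(tax$taxon_id, resident)

    prev_factor <- if (cfg$mode == "wes_like") cfg$wes_prevalence_factor else 1
    depth_factor <- if (cfg$mode == "wes_like") cfg$wes_depth_factor else 1
    mu <- max(2.5, cfg$nb_mean * depth_factor)

    meta <- simulate_metadata(cfg)
    msi <- meta$msi_status == "MSI"

    tumor_ids <- meta$sample_id
    blood_ids <- sprintf("%s_%s_blood_%03d", cfg$cohort,
                         substr(cfg$mode, 1, 3), seq_len(cfg$n_blood))

    # per-sample x species log2 fold effects on tumor latent abundance:
    # presence odds and negative-binomial mean both scale by 2^lfc, so a
    # planted fold change survives the two-read detection rule in either
    # direction
    effect_lfc <- matrix(0, cfg$n_tumor, nrow(tax),
                         dimnames = list(tumor_ids, tax$taxon_id))
    if (!is.null(cfg$covariate_effects) && nrow(cfg$covariate_effects)) {
      comparison <- list(
        sex = meta$sex == "male",
        pT = meta$pT %in% c("3", "4"),
        geography = meta$geography == "asia",
        msi_status = msi
      )
      eff <- cfg$covariate_effects
      for (i in seq_len(nrow(eff))) {
        flag <- comparison[[eff$covariate[i]]]
        flag[is.na(flag)] <- FALSE
        effect_lfc[flag, eff$species[i]] <-
          effect_lfc[flag, eff$species[i]] + eff$log2fc[i]
      }
    }

    draw_material <- function(ids, p_res, p_con, msi_flags = NULL,
                              lfc = NULL) {
      n <- length(ids)
      k <- nrow(tax)
      p <- matrix(rep(c(rep(p_res, cfg$n_resident_species),
                        rep(p_con, cfg$n_contaminant_species)), each = n),
                  nrow = n)
      if (!is.null(msi_flags) && cfg$msi_richness_boost > 0) {
        boost <- outer(msi_flags, tax$taxon_id %in% resident) *
          cfg$msi_richness_boost
        p <- pmin(1, p + boost)
      }
      mu_mat <- matrix(mu, n, k)
      if (!is.null(lfc) && any(lfc != 0)) {
        fc <- 2^lfc
        odds <- p / (1 - p) * fc
        shifted <- odds / (1 + odds)
        p <- ifelse(lfc != 0 & p < 1, shifted, p)
        mu_mat <- pmax(2.5, mu_mat * fc)
      }
      present <- matrix(stats::rbinom(n * k, 1L, as.vector(p)), nrow = n)
      counts <- matrix(0, n, k, dimnames = list(ids, tax$taxon_id))
      idx <- which(present == 1L)
      counts[idx] <- 2 + stats::rnbinom(length(idx), mu = mu_mat[idx] - 2,
                                        size = cfg$nb_dispersion)
      counts
    }

    tumor <- draw_material(tumor_ids,
                           cfg$resident_tissue_prevalence * prev_factor,
                           cfg$contaminant_prevalence * prev_factor,
                           msi_flags = msi, lfc = effect_lfc)
    blood <- draw_material(blood_ids,
                           cfg$resident_blood_prevalence * prev_factor,
                           cfg$contaminant_prevalence * prev_factor)

    if (cfg$msi_abundance_multiplier != 1 && any(msi)) {
      res_cols <- tax$taxon_id %in% resident
      tumor[msi, res_cols] <- round(tumor[msi, res_cols] *
                                      cfg$msi_abundance_multiplier)
    }

    truth <- list(
      resident_species = resident,
      contaminant_species = contaminant,
      subtype = stats::setNames(meta$.latent_subtype, meta$sample_id),
      effects = cfg$covariate_effects
    )
    meta$.latent_subtype <- NULL

    list(
      tumor = abundance_matrix(tumor, "unambiguous_reads", "tumor"),
      blood = abundance_matrix(blood, "unambiguous_reads", "blood"),
      tumor_score = abundance_matrix(tumor, "score", "tumor"),
      blood_score = abundance_matrix(blood, "score", "blood"),
      metadata = meta,
      taxonomy = tax,
      truth = truth
    )
  })
}

simulate_metadata <- function(cfg) {
  n <- cfg$n_tumor
  ids <- sprintf("%s_%s_tumor_%03d", cfg$cohort, substr(cfg$mode, 1, 3),
                 seq_len(n))
  gs_fraction <- 1 - cfg$msi_fraction - cfg$ebv_fraction - cfg$cin_fraction
  subtype <- sample(c("EBV", "MSI", "CIN", "GS"), n, replace = TRUE,
                    prob = c(cfg$ebv_fraction, cfg$msi_fraction,
                             cfg$cin_fraction, gs_fraction))
  msi <- subtype == "MSI"
  # SCV consistent with MSI: hypermutated >= 20/Mb, the rest well below
  scv <- ifelse(msi, 20 + stats::rexp(n, 1 / 30),
                pmin(19.5, stats::rexp(n, 1 / 5)))
  ebv <- ifelse(subtype == "EBV", 1e-3 * (1 + stats::rexp(n, 1)),
                stats::runif(n, 0, 5e-5))
  ploidy <- ifelse(subtype == "CIN", stats::runif(n, 2.6, 4.5),
                   stats::runif(n, 1.8, 2.4))
  purity <- stats::runif(n, 0.2, 0.9)
  human_reads <- round(stats::runif(n, 6e8, 1.2e9))

  meta <- tibble::tibble(
    sample_id = ids,
    cohort = factor(cfg$cohort, levels = gc_enum_levels$cohort),
    age = round(pmax(30, pmin(95, stats::rnorm(n, 68, 10)))),
    sex = factor(sample(c("male", "female"), n, TRUE, c(0.65, 0.35)),
                 levels = gc_enum_levels$sex),
    location = factor(sample(c("cardia", "non_cardia"), n, TRUE, c(0.35, 0.65)),
                      levels = gc_enum_levels$location),
    geography = factor(
      if (cfg$mode == "wgs_like") rep("not_asia", n) else
        sample(c("asia", "not_asia"), n, TRUE, c(0.2, 0.8)),
      levels = gc_enum_levels$geography),
    pT = factor(sample(c("1", "2", "3", "4"), n, TRUE, c(0.1, 0.2, 0.5, 0.2)),
                levels = gc_enum_levels$pT),
    pN = factor(sample(c("0", "1", "2", "3"), n, TRUE, c(0.35, 0.25, 0.25, 0.15)),
                levels = gc_enum_levels$pN),
    histology = factor(
      sample(c("diffuse", "intestinal", "mixed", "mucinous"), n, TRUE,
             c(0.3, 0.5, 0.15, 0.05)), levels = gc_enum_levels$histology),
    msi_status = factor(ifelse(msi, "MSI", "MSS"),
                        levels = gc_enum_levels$msi_status),
    scv_per_mb = scv,
    ebv_per_human_cell = ebv,
    ploidy = ploidy,
    purity = purity,
    human_reads = human_reads,
    .latent_subtype = subtype
  )
  if (cfg$mode == "wes_like") {
    meta$human_reads <- NA_real_
    meta$ploidy <- NA_real_
    meta$purity <- NA_real_
  }
  meta
}

#' Analytic presence probability for a planted species class
#'
#' Returns the presence probability the generator uses for the given
#' species class and material under `config`, including the detection
#' penalty of `wes_like` mode. Because counts given presence always reach
#' the two-read prevalence rule, this is exactly the expected prevalence
#' the decontamination stage observes; it serves as the analytic oracle in
#' recovery tests.
#'
#' @param config A [cohort_config()].
#' @param species_class `"resident"` or `"contaminant"`.
#' @param material `"tumor"` or `"blood"`.
#' @return A probability.
#' @export
expected_prevalence <- function(config, species_class = c("resident", "contaminant"),
                                material = c("tumor", "blood")) {
  species_class <- match.arg(species_class)
  material <- match.arg(material)
  factor <- if (config$mode == "wes_like") config$wes_prevalence_factor else 1
  base <- if (species_class == "contaminant") config$contaminant_prevalence
  else if (material == "tumor") config$resident_tissue_prevalence
  else config$resident_blood_prevalence
  base * factor
}
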