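#' Configuration for the synthetic methylation generators
#'
#' Bundles the generator parameters with defaults chosen to emulate the
#' study conditions the analysis methods assume: a two-reference library
#' separated by a mean absolute beta difference (`reference_gap`) at the
#' informative CpGs, per-sample mixing/intermediacy weights drawn from a
#' bimodal distribution (normals at 0.45 and 0.9, sd 0.08, truncated to
#' \[0, 1\]), and beta-scale noise added as clipped normal deviates.
#'
#' @param n_cpgs Total CpGs in the library.
#' @param n_informative CpGs that separate the two references.
#' @param reference_gap Mean absolute beta difference at informative CpGs.
#' @param noise_sd Beta-scale noise standard deviation.
#' @param n_samples Cohort size.
#' @param w Optional fixed per-sample weights; `NULL` draws from the
#'   bimodal default.
#' @param n_filler Additional independent filler cell types in the
#'   reference library (0 for a pure two-type library, 10 for the 12-type
#'   layout).
#' @param mem_type,nv_type Names of the two endpoint reference columns.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_cpgs = 1000, n_informative = 600,
                         reference_gap = 0.5, noise_sd = 0.02,
                         n_samples = 30, w = NULL, n_filler = 0,
                         mem_type = "B-memory", nv_type = "B-naive") {
  stopifnot(n_cpgs >= n_informative, n_informative >= 0,
            reference_gap > 0, reference_gap < 1, noise_sd >= 0,
            n_samples >= 1, n_filler >= 0)
  structure(list(n_cpgs = n_cpgs, n_informative = n_informative,
                 reference_gap = reference_gap, noise_sd = noise_sd,
                 n_samples = n_samples, w = w, n_filler = n_filler,
                 mem_type = mem_type, nv_type = nv_type),
            class = "synth_config")
}

# run expr with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

draw_w <- function(n) {
  mu <- ifelse(stats::runif(n) < 0.5, 0.45, 0.9)
  pmin(pmax(stats::rnorm(n, mu, 0.08), 0), 1)
}

# bimodal background betas (most CpGs near 0 or near 1)
draw_background_beta <- function(n) {
  lo <- stats::rbeta(n, 2, 10)
  hi <- stats::rbeta(n, 10, 2)
  ifelse(stats::runif(n) < 0.5, lo, hi)
}

add_beta_noise <- function(x, sd) {
  if (sd == 0) return(x)
  pmin(pmax(x + stats::rnorm(length(x), 0, sd), 0), 1)
}

#' Generate a two-reference library (plus optional filler cell types)
#'
#' Informative CpGs get per-CpG absolute differences drawn around
#' `reference_gap` (normal, sd 0.05), placed symmetrically about a random
#' midpoint with random direction, so one type sits near high beta and the
#' other near low beta; the remaining CpGs share a common bimodal
#' background value across types. Filler types deviate independently from
#' the background at a random 20% of CpGs.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed; identical `cfg` + `seed` give bitwise
#'   identical output.
#' @return Reference matrix (CpGs x cell types) with attributes
#'   `informative` (CpG ids) and `realized_gap`.
#' @export
make_reference_pair <- function(cfg, seed) {
  with_seed(seed, {
    n <- cfg$n_cpgs; ni <- cfg$n_informative
    cpgs <- sprintf("cg%06d", seq_len(n))
    base <- draw_background_beta(n)
    mem <- base; nv <- base
    if (ni > 0) {
      idx <- seq_len(ni)
      delta <- pmin(pmax(stats::rnorm(ni, cfg$reference_gap, 0.05), 0.05), 0.98)
      mid <- stats::runif(ni, 0.4, 0.6)
      sgn <- ifelse(stats::runif(ni) < 0.5, 1, -1)
      mem_i <- mid + sgn * delta / 2
      nv_i <- mid - sgn * delta / 2
      if (any(mem_i < 0 | mem_i > 1 | nv_i < 0 | nv_i > 1))
        warning("reference gap incompatible with [0,1] at some CpGs; clipped")
      mem[idx] <- pmin(pmax(mem_i, 0), 1)
      nv[idx] <- pmin(pmax(nv_i, 0), 1)
    }
    ref <- cbind(mem, nv)
    colnames(ref) <- c(cfg$mem_type, cfg$nv_type)
    if (cfg$n_filler > 0) {
      fill <- sapply(seq_len(cfg$n_filler), function(k) {
        v <- base
        alt <- stats::runif(n) < 0.2
        v[alt] <- draw_background_beta(sum(alt))
        v
      })
      colnames(fill) <- paste0("Filler-", seq_len(cfg$n_filler))
      ref <- cbind(ref, fill)
    }
    rownames(ref) <- cpgs
    attr(ref, "informative") <- cpgs[seq_len(ni)]
    attr(ref, "realized_gap") <- if (ni > 0)
      mean(abs(ref[seq_len(ni), cfg$mem_type] - ref[seq_len(ni), cfg$nv_type]))
      else 0
    ref
  })
}

#' Generate a cohort of per-CpG intermediate-state samples
#'
#' Realizes the single-population hypothesis: for a sample with weight `w`,
#' each informative CpG independently adopts the memory-type reference
#' value with probability `w` and the naive-type value otherwise;
#' non-informative CpGs take the (shared) reference value. Clipped normal
#' noise of sd `noise_sd` is added throughout.
#'
#' @inheritParams make_reference_pair
#' @param ref Reference from [make_reference_pair()] (two-type part used).
#' @return List: `betas` (CpGs x samples), `truth` (list with per-sample
#'   `w`, and `states` — logical informative-CpGs x samples matrix, TRUE =
#'   memory state).
#' @export
make_intermediate_cohort <- function(cfg, ref, seed) {
  with_seed(seed, {
    w <- if (is.null(cfg$w)) draw_w(cfg$n_samples) else rep_len(cfg$w, cfg$n_samples)
    info <- attr(ref, "informative")
    mem <- ref[, cfg$mem_type]; nv <- ref[, cfg$nv_type]
    ii <- match(info, rownames(ref))
    states <- matrix(FALSE, length(ii), cfg$n_samples)
    for (j in seq_len(cfg$n_samples))
      states[, j] <- stats::runif(length(ii)) < w[j]
    betas <- sapply(seq_len(cfg$n_samples), function(j) {
      v <- mem  # equals nv outside the informative set
      v[ii] <- ifelse(states[, j], mem[ii], nv[ii])
      v
    })
    betas <- matrix(betas, nrow = nrow(ref))
    betas <- apply(betas, 2, add_beta_noise, sd = cfg$noise_sd)
    dimnames(betas) <- list(rownames(ref),
                            sprintf("S%03d", seq_len(cfg$n_samples)))
    rownames(states) <- info
    colnames(states) <- colnames(betas)
    list(betas = betas, truth = list(w = w, states = states))
  })
}

#' Generate a cohort of true two-population mixtures
#'
#' Realizes the alternative hypothesis: each sample is the weighted average
#' `w * beta_mem + (1 - w) * beta_nv` at every CpG, plus clipped normal
#' noise.
#'
#' @inheritParams make_intermediate_cohort
#' @return List: `betas`, `truth` (per-sample `w`).
#' @export
make_mixture_cohort <- function(cfg, ref, seed) {
  with_seed(seed, {
    w <- if (is.null(cfg$w)) draw_w(cfg$n_samples) else rep_len(cfg$w, cfg$n_samples)
    mem <- ref[, cfg$mem_type]; nv <- ref[, cfg$nv_type]
    betas <- sapply(w, function(wj) add_beta_noise(wj * mem + (1 - wj) * nv,
                                                   cfg$noise_sd))
    dimnames(betas) <- list(rownames(ref),
                            sprintf("S%03d", seq_len(cfg$n_samples)))
    list(betas = betas, truth = list(w = w))
  })
}

#' Generate an EWAS cohort with known covariate effects
#'
#' M-values follow `M_g = beta0_g + dm_g * v + a * age_c + s * sex + eps`,
#' with `eps ~ N(0, sigma_g^2)` and per-CpG variances drawn from a scaled
#' inverse-chi-square (`sigma_g^2 = d0 * s0_sq / chisq(d0)`), the prior the
#' moderation step assumes. A fraction `prop_effect` of CpGs carries the
#' effect `effect` on the M scale (half positive, half negative); the rest
#' are null.
#'
#' @param n_cpgs,n_samples Problem size.
#' @param prop_effect Fraction of CpGs with a true effect (default 0.1).
#' @param effect True |Delta M| per unit of the variable (default 1.5).
#' @param d0,s0_sq Variance prior (default 4 and 0.05); set `d0 = Inf` for
#'   a common variance `s0_sq`.
#' @param age_effect,sex_effect M-value effects of the adjusters.
#' @param seed Integer seed.
#' @return List: `m` (M-value matrix), `meta` (data frame: `sample_id`,
#'   `v`, `age`, `sex`), `truth` (list: `effect_cpgs`, `dm`, `sigma2`,
#'   `beta0`).
#' @export
make_ewas_cohort <- function(n_cpgs = 2000, n_samples = 40,
                             prop_effect = 0.1, effect = 1.5,
                             d0 = 4, s0_sq = 0.05,
                             age_effect = 0.02, sex_effect = 0.3, seed) {
  with_seed(seed, {
    cpgs <- sprintf("cg%06d", seq_len(n_cpgs))
    ids <- sprintf("S%03d", seq_len(n_samples))
    v <- stats::rnorm(n_samples)
    age <- round(stats::rnorm(n_samples, 70, 9))
    sex <- sample(c("F", "M"), n_samples, replace = TRUE)
    if (length(unique(sex)) == 1) sex[1] <- setdiff(c("F", "M"), sex[1])
    sex_ind <- as.numeric(sex == "M")
    age_c <- age - mean(age)

    beta0 <- ifelse(stats::runif(n_cpgs) < 0.5,
                    stats::rnorm(n_cpgs, -2, 1), stats::rnorm(n_cpgs, 2, 1))
    dm <- numeric(n_cpgs)
    n_eff <- round(prop_effect * n_cpgs)
    if (n_eff > 0)
      dm[seq_len(n_eff)] <- effect * rep_len(c(1, -1), n_eff)
    sigma2 <- if (is.infinite(d0)) rep(s0_sq, n_cpgs) else
      d0 * s0_sq / stats::rchisq(n_cpgs, df = d0)

    mu <- outer(beta0, rep(1, n_samples)) + outer(dm, v) +
      outer(rep(age_effect, n_cpgs), age_c) +
      outer(rep(sex_effect, n_cpgs), sex_ind)
    eps <- matrix(stats::rnorm(n_cpgs * n_samples, 0, sqrt(sigma2)),
                  n_cpgs, n_samples)
    m <- mu + eps
    dimnames(m) <- list(cpgs, ids)
    meta <- data.frame(sample_id = ids, v = v, age = age, sex = sex,
                       stringsAsFactors = FALSE)
    list(m = m, meta = meta,
         truth = list(effect_cpgs = cpgs[dm != 0], dm = dm,
                      sigma2 = sigma2, beta0 = beta0))
  })
}

#' Generate purified donor groups and a case group for equivalence testing
#'
#' Donor profiles are the reference column plus within-group noise. The
#' case group tracks the memory reference at a planted fraction of CpGs
#' (the equivalence structure the TOST screen should recover) and sits
#' midway between the two references elsewhere.
#'
#' @inheritParams make_intermediate_cohort
#' @param n_donors Donors per reference group (default 6).
#' @param n_cases Case samples (default 24).
#' @param equiv_frac Fraction of CpGs where the cases track the memory
#'   reference (default 0.7).
#' @param within_sd Within-group beta noise sd (default 0.02).
#' @return List: `mem_donors`, `nv_donors`, `cases` (beta matrices),
#'   `truth` (list: `equiv_cpgs`).
#' @export
make_donor_groups <- function(cfg, ref, seed, n_donors = 6, n_cases = 24,
                              equiv_frac = 0.7, within_sd = 0.02) {
  with_seed(seed, {
    mem <- ref[, cfg$mem_type]; nv <- ref[, cfg$nv_type]
    n <- nrow(ref)
    grp <- function(center, k, prefix) {
      x <- sapply(seq_len(k), function(j) add_beta_noise(center, within_sd))
      dimnames(x) <- list(rownames(ref), sprintf("%s%02d", prefix, seq_len(k)))
      x
    }
    n_eq <- round(equiv_frac * n)
    eq <- sort(sample.int(n, n_eq))
    case_center <- (mem + nv) / 2
    case_center[eq] <- mem[eq]
    list(mem_donors = grp(mem, n_donors, "MD"),
         nv_donors = grp(nv, n_donors, "ND"),
         cases = grp(case_center, n_cases, "CASE"),
         truth = list(equiv_cpgs = rownames(ref)[eq]))
  })
}

#' Generate a CpG annotation table with a planted TFBS enrichment
#'
#' Chromosome, island context, probe type and genomic context are assigned
#' independently from configurable marginals. One TFBS feature is planted:
#' background CpGs belong to it with probability `base_rate`, foreground
#' CpGs with probability `fold * base_rate` (an error if that exceeds 1).
#' Additional null TFBS features with the background rate everywhere can
#' be requested for FDR calibration.
#'
#' @param cpg_ids CpG identifiers (the background universe).
#' @param foreground CpG ids to receive the planted enrichment.
#' @param fold Membership-rate fold of foreground over background
#'   (default 3; 1 plants nothing).
#' @param base_rate Background TFBS membership probability (default 0.05).
#' @param n_null_features Extra unenriched TFBS features (default 0).
#' @param seed Integer seed.
#' @param island_marginals,probe_marginals,context_marginals Named
#'   probability vectors over the closed vocabularies (must each sum to 1).
#' @param n_chromosomes Chromosomes assigned uniformly (default 22).
#' @return List: `ann` (annotation data frame), `tfbs_sets` (named list;
#'   planted feature is `"TF_planted"`), `truth` (planted fold and rate).
#' @export
make_annotation <- function(cpg_ids, foreground = character(0), fold = 3,
                            base_rate = 0.05, n_null_features = 0, seed,
                            island_marginals = c(Island = 0.3, Shore = 0.25,
                                                 Shelf = 0.1, OpenSea = 0.35),
                            probe_marginals = c(I = 0.25, II = 0.75),
                            context_marginals = c(Promoter = 0.25, `5'UTR` = 0.05,
                                                  `3'UTR` = 0.05, Exon = 0.1,
                                                  Intron = 0.3, Intergenic = 0.25),
                            n_chromosomes = 22) {
  stopifnot(abs(sum(island_marginals) - 1) < 1e-9,
            abs(sum(probe_marginals) - 1) < 1e-9,
            abs(sum(context_marginals) - 1) < 1e-9)
  if (fold * base_rate > 1)
    stop("fold * base_rate exceeds 1; enrichment infeasible")
  if (!all(foreground %in% cpg_ids))
    stop("foreground must be a subset of cpg_ids")
  with_seed(seed, {
    n <- length(cpg_ids)
    ann <- data.frame(
      cpg_id = cpg_ids,
      chromosome = paste0("chr", sample.int(n_chromosomes, n, replace = TRUE)),
      island_context = sample(names(island_marginals), n, TRUE,
                              prob = island_marginals),
      probe_type = sample(names(probe_marginals), n, TRUE,
                          prob = probe_marginals),
      genomic_context = sample(names(context_marginals), n, TRUE,
                               prob = context_marginals),
      stringsAsFactors = FALSE)
    rate <- rep(base_rate, n)
    rate[cpg_ids %in% foreground] <- fold * base_rate
    sets <- list(TF_planted = cpg_ids[stats::runif(n) < rate])
    if (n_null_features > 0) {
      nulls <- lapply(seq_len(n_null_features), function(k)
        cpg_ids[stats::runif(n) < base_rate])
      names(nulls) <- paste0("TF_null_", seq_len(n_null_features))
      sets <- c(sets, nulls)
    }
    list(ann = ann, tfbs_sets = sets,
         truth = list(fold = fold, base_rate = base_rate))
  })
}
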