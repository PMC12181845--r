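#' Default focal-group rules
#'
#' Maps ASV taxa to the four focal parasite groups analysed for richness:
#' chytrids (Chytridiomycota), aphelids (Aphelidiomycota), Peronosporomycetes
#' (drawn from Gyrista in the protist dataset) and Cryptomycota. Fungal
#' groups are taken from the fungal marker dataset only.
#'
#' @return data.frame with columns `taxon`, `group`, `dataset`.
#' @export
default_focal_rules <- function() {
  data.frame(
    taxon = c("Chytridiomycota", "Aphelidiomycota", "Peronosporomycetes",
              "Cryptomycota"),
    group = c("chytrids", "aphelids", "peronosporomycetes", "cryptomycota"),
    dataset = c("fungal", "fungal", "protist", "fungal"),
    stringsAsFactors = FALSE
  )
}

# host groups considered terrestrial for the aquatic-host selection rule
.terrestrial_host_groups <- c("terrestrial_plants", "humans",
                              "terrestrial_metazoans")

#' Assign parasite ASVs to focal richness groups
#'
#' Selects, among parasite calls, the ASVs belonging to the focal groups
#' (default [default_focal_rules()]), matching each rule's taxon against the
#' ASV's lineage within the rule's marker dataset. ASVs whose host groups
#' are exclusively terrestrial (terrestrial plants, humans, terrestrial
#' metazoans) are excluded. Chytrids with salamander hosts stay in the
#' richness group but are flagged for exclusion from the host-richness
#' correlation analysis (salamander host richness is not surveyed).
#'
#' @param calls `parasite_calls` data.frame.
#' @param taxa data.frame with columns `asv_id`, `lineage`, `dataset` giving
#'   each ASV's own taxonomy (from the best-hit record lineage or a
#'   dataset-native assignment).
#' @param rules Focal-group rule table; unknown columns raise a
#'   configuration error.
#' @return data.frame: `asv_id`, `group`, `exclude_from_host_corr`.
#' @export
select_focal_groups <- function(calls, taxa, rules = default_focal_rules()) {
  if (!all(c("taxon", "group", "dataset") %in% names(rules))) {
    stop("focal rules must have columns taxon, group, dataset", call. = FALSE)
  }
  par <- calls[calls$status == "parasite", , drop = FALSE]
  if (!nrow(par)) {
    return(data.frame(asv_id = character(0), group = character(0),
                      exclude_from_host_corr = logical(0)))
  }
  tx <- taxa[match(par$asv_id, taxa$asv_id), ]
  out <- list()
  for (r in seq_len(nrow(rules))) {
    in_taxon <- grepl(rules$taxon[r], tx$lineage, fixed = TRUE)
    in_ds <- if (is.na(rules$dataset[r])) TRUE else tx$dataset == rules$dataset[r]
    cand <- which(in_taxon & in_ds)
    if (!length(cand)) next
    hg <- lapply(par$host_groups[cand], split_multi)
    terrestrial_only <- vapply(hg, function(g) {
      length(g) > 0 && all(g %in% .terrestrial_host_groups)
    }, logical(1))
    keep <- cand[!terrestrial_only]
    if (!length(keep)) next
    sala <- vapply(par$host_groups[keep], function(g) {
      "salamanders" %in% split_multi(g)
    }, logical(1))
    out[[length(out) + 1L]] <- data.frame(
      asv_id = par$asv_id[keep], group = rules$group[r],
      exclude_from_host_corr = rules$group[r] == "chytrids" & sala,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(asv_id = character(0), group = character(0),
                      exclude_from_host_corr = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample richness table for focal groups
#'
#' Richness of a group in a sample is the number of distinct ASVs of that
#' group with a non-zero count. When `host_asvs` is supplied, an additional
#' `host_richness` column counts the present ASVs of the host subdivisions
#' (green algae, charophytes, chromists, gyristans, dinoflagellates in the
#' intended use).
#'
#' @param counts Decontaminated count matrix, samples x ASVs.
#' @param assignment data.frame `asv_id`, `group` (from
#'   [select_focal_groups()]).
#' @param metadata Sample metadata covering every row of `counts`.
#' @param host_asvs Optional character vector of host-group ASV ids.
#' @return data.frame: sample metadata columns plus one richness column per
#'   group and optionally `host_richness`.
#' @export
compute_richness <- function(counts, assignment, metadata, host_asvs = NULL) {
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing)) {
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  md <- metadata[match(rownames(counts), metadata$sample_id),
                 intersect(c("sample_id", "lake", "lake_type", "season",
                             "year", "run"), names(metadata))]
  pa <- counts >= 1
  for (g in unique(assignment$group)) {
    ids <- intersect(assignment$asv_id[assignment$group == g],
                     colnames(counts))
    md[[g]] <- as.integer(rowSums(pa[, ids, drop = FALSE]))
  }
  if (!is.null(host_asvs)) {
    ids <- intersect(host_asvs, colnames(counts))
    md$host_richness <- as.integer(rowSums(pa[, ids, drop = FALSE]))
  }
  rownames(md) <- NULL
  md
}

#' Fit a Poisson richness model with Type-III Wald tests
#'
#' Fits `richness ~ lake_type * season` (plus `log(host_richness + 1)` when
#' `include_host`) with a Poisson log link and sum-to-zero factor contrasts,
#' and computes per-term Type-III Wald chi-square tests. Random intercepts
#' (`lake`, `run`, `year`) are honoured through a mixed-effects fit when
#' requested; a singular or failed mixed fit falls back to the
#' fixed-effects-only model, recorded in `meta$backend` and
#' `meta$reduced_random_effects`.
#'
#' @param table Richness table from [compute_richness()].
#' @param group Name of the richness column to model.
#' @param include_host Add log-transformed host richness as a covariate.
#' @param random_terms Character subset of `c("lake", "run", "year")`;
#'   empty (default) fits a fixed-effects GLM.
#' @param interaction Include the lake_type x season interaction (default
#'   TRUE).
#' @return Object of class `richness_fit`: the underlying fit, the Type-III
#'   Wald table (`anova`), deviances, and fit metadata.
#' @export
fit_richness_model <- function(table, group, include_host = FALSE,
                               random_terms = character(0),
                               interaction = TRUE) {
  stopifnot(group %in% names(table))
  dat <- table
  dat$lake_type <- factor(dat$lake_type)
  if (!is.factor(dat$season)) {
    dat$season <- factor(dat$season, levels = unique(dat$season))
  }
  dat$.y <- dat[[group]]
  if (nlevels(droplevels(dat$lake_type)) < 2 ||
      nlevels(droplevels(dat$season)) < 2) {
    stop("need >= 2 lake types and >= 2 seasons", call. = FALSE)
  }
  if (any(dat$.y < 0) || any(dat$.y != round(dat$.y))) {
    stop("richness must be non-negative integers", call. = FALSE)
  }
  if (include_host) {
    if (is.null(dat$host_richness)) stop("no host_richness column", call. = FALSE)
    dat$log_host_richness <- log(dat$host_richness + 1)
  }
  fixed <- if (interaction) "lake_type * season" else "lake_type + season"
  if (include_host) fixed <- paste(fixed, "+ log_host_richness")
  contrasts_arg <- list(lake_type = "contr.sum", season = "contr.sum")
  if ("year" %in% names(dat)) dat$year <- factor(dat$year)
  if ("run" %in% names(dat)) dat$run <- factor(dat$run)

  meta <- list(contrasts = "contr.sum", backend = "glm",
               reduced_random_effects = FALSE, converged = TRUE,
               random_terms = random_terms)
  fit <- NULL
  if (length(random_terms)) {
    ranef <- paste(sprintf("(1 | %s)", random_terms), collapse = " + ")
    form <- stats::as.formula(paste(".y ~", fixed, "+", ranef))
    mix <- tryCatch(
      lme4::glmer(form, data = dat, family = stats::poisson(),
                  contrasts = contrasts_arg),
      error = function(e) e, warning = function(w) w)
    if (inherits(mix, "merMod") && !lme4::isSingular(mix, tol = 1e-4)) {
      fit <- mix
      meta$backend <- "glmer"
    } else {
      meta$reduced_random_effects <- TRUE
    }
  }
  if (is.null(fit)) {
    form <- stats::as.formula(paste(".y ~", fixed))
    fit <- stats::glm(form, data = dat, family = stats::poisson(),
                      contrasts = contrasts_arg)
    meta$converged <- fit$converged
  }

  an <- car::Anova(fit, type = 3, test.statistic = "Wald")
  an <- as.data.frame(an)
  names(an)[names(an) == "Chisq"] <- "chisq"
  names(an)[grepl("^Pr", names(an))] <- "p_value"
  an$term <- rownames(an)
  rownames(an) <- NULL

  dev <- if (meta$backend == "glm") stats::deviance(fit) else NA_real_
  nulldev <- if (meta$backend == "glm") fit$null.deviance else NA_real_

  structure(list(fit = fit, anova = an[, c("term", "chisq", "Df", "p_value")],
                 group = group, formula = form, data = dat,
                 deviance = dev, null_deviance = nulldev,
                 contrasts_arg = contrasts_arg, include_host = include_host,
                 interaction = interaction, meta = meta),
            class = "richness_fit")
}

#' @export
print.richness_fit <- function(x, ...) {
  cat(sprintf("Poisson richness model for '%s' (%s backend%s)\n", x$group,
              x$meta$backend,
              if (x$meta$reduced_random_effects)
                "; random effects dropped: singular/failed mixed fit" else ""))
  cat("  ", deparse(x$formula), "\n")
  cat("Type-III Wald tests (sum-to-zero contrasts):\n")
  print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.richness_fit <- function(object, ...) {
  list(coefficients = stats::coef(summary(object$fit)),
       anova = object$anova,
       deviance = object$deviance,
       null_deviance = object$null_deviance,
       meta = object$meta)
}

#' @export
coef.richness_fit <- function(object, ...) {
  if (object$meta$backend == "glmer") lme4::fixef(object$fit)
  else stats::coef(object$fit)
}

#' Heated-vs-control log richness ratio from a fitted model
#'
#' The marginal lake-type contrast: the difference in linear predictor
#' between heated and control lakes averaged over the observed seasons
#' (and, when present, at the mean log host richness), with its Wald
#' standard error and confidence interval. Under a multiplicative habitat
#' effect m on expected richness this estimates log(m) regardless of the
#' contrast scheme.
#'
#' @param x A `richness_fit`.
#' @param level Confidence level (default 0.95).
#' @return List: `estimate`, `se`, `lower`, `upper`.
#' @export
lake_type_contrast <- function(x, level = 0.95) {
  stopifnot(inherits(x, "richness_fit"))
  dat <- x$data
  grid <- expand.grid(lake_type = levels(dat$lake_type),
                      season = levels(droplevels(dat$season)),
                      KEEP.OUT.ATTRS = FALSE)
  if (x$include_host) grid$log_host_richness <- mean(dat$log_host_richness)
  fixed <- if (x$interaction) "~ lake_type * season" else "~ lake_type + season"
  if (x$include_host) fixed <- paste(fixed, "+ log_host_richness")
  X <- stats::model.matrix(stats::as.formula(fixed), data = grid,
                           contrasts.arg = x$contrasts_arg)
  cvec <- colMeans(X[grid$lake_type == "heated", , drop = FALSE]) -
    colMeans(X[grid$lake_type == "control", , drop = FALSE])
  beta <- coef(x)
  V <- as.matrix(stats::vcov(x$fit))
  cvec <- cvec[names(beta)]
  est <- sum(cvec * beta)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se, lower = est - z * se, upper = est + z * se)
}

#' Deviance-based partial R-squared
#'
#' For a full model and the nested reduced model lacking exactly one term,
#' the proportional reduction in residual deviance:
#' `(deviance_reduced - deviance_full) / deviance_reduced`, clipped to
#' `[0, 1]`.
#'
#' @param full,reduced `richness_fit` objects (GLM backend) or `glm` fits on
#'   the same data, `reduced` nested in `full`.
#' @return The partial R-squared.
#' @export
partial_r2 <- function(full, reduced) {
  get_fit <- function(x) {
    if (inherits(x, "richness_fit")) {
      if (x$meta$backend != "glm") {
        stop("partial_r2 requires a fixed-effects (GLM) fit", call. = FALSE)
      }
      x$fit
    } else x
  }
  f <- get_fit(full); r <- get_fit(reduced)
  tf <- attr(stats::terms(f), "term.labels")
  tr <- attr(stats::terms(r), "term.labels")
  if (!all(tr %in% tf) || length(setdiff(tf, tr)) != 1L) {
    stop("`reduced` must be `full` minus exactly one term", call. = FALSE)
  }
  if (stats::nobs(f) != stats::nobs(r)) {
    stop("models must be fitted on the same data", call. = FALSE)
  }
  df <- stats::deviance(f); dr <- stats::deviance(r)
  if (dr <= 0) return(if (df < dr) 1 else 0)
  max(0, min(1, (dr - df) / dr))
}

#' Per-lake-type host-richness GLMs with partial R-squared
#'
#' Post-hoc fixed-effects analysis of the host-diversity/parasite-diversity
#' relationship: for each lake type separately, fits
#' `richness ~ log(host_richness + 1) + season` (Poisson) and reports each
#' term's Type-III Wald test and deviance partial R-squared.
#'
#' @param table Richness table with `host_richness`.
#' @param group Richness column to model (default `"chytrids"`).
#' @return data.frame: `lake_type`, `term`, `chisq`, `p_value`,
#'   `partial_r2`.
#' @export
host_correlation_posthoc <- function(table, group = "chytrids") {
  stopifnot(group %in% names(table), "host_richness" %in% names(table))
  out <- list()
  for (lt in unique(table$lake_type)) {
    dat <- table[table$lake_type == lt, , drop = FALSE]
    dat$season <- factor(dat$season, levels = unique(dat$season))
    dat$log_host_richness <- log(dat$host_richness + 1)
    dat$.y <- dat[[group]]
    full <- stats::glm(.y ~ log_host_richness + season, data = dat,
                       family = stats::poisson(),
                       contrasts = list(season = "contr.sum"))
    no_host <- stats::glm(.y ~ season, data = dat, family = stats::poisson(),
                          contrasts = list(season = "contr.sum"))
    no_season <- stats::glm(.y ~ log_host_richness, data = dat,
                            family = stats::poisson())
    an <- as.data.frame(car::Anova(full, type = 3, test.statistic = "Wald"))
    out[[length(out) + 1L]] <- data.frame(
      lake_type = lt,
      term = c("host_richness", "season"),
      chisq = an[c("log_host_richness", "season"), "Chisq"],
      p_value = an[c("log_host_richness", "season"), "Pr(>Chisq)"],
      partial_r2 = c(partial_r2(full, no_host), partial_r2(full, no_season)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
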