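# End-to-end orchestration: build the score table (PD + PS per species) and
# run every behavioral analysis against it.

#' Score candidate species by PD and PS
#'
#' Builds the per-species score table: phylogenetic distance (PD) of each
#' taxon to the host on a rooted tree (built by JC69 + neighbor-joining from
#' the gene alignments, or supplied externally), and physicochemical
#' similarity (PS) of each species' volatile blend to the host kairomone
#' targets. The host must be present in both the tree and the blends before
#' any computation starts.
#'
#' @param host Host taxon label.
#' @param blends Named list of `blend` objects (must include the host).
#' @param genes List of `gene_alignment` objects (ignored when `tree` given).
#' @param tree Optional externally inferred tree (`phylo` or Newick path);
#'   rooted trees are used as-is, unrooted ones are rooted by `rooting`.
#' @param targets Target `blend` (defaults to the packaged isothiocyanates).
#' @param rooting `"midpoint"` or `"outgroup"`.
#' @param outgroup Outgroup taxon when `rooting = "outgroup"`.
#' @param distance_model `"jc69"` or `"p_distance"`.
#' @param aggregator PS aggregator, see [blend_similarity()].
#' @param out_csv Optional path; writes the table sorted by species.
#' @return Data frame of class `score_table`: `species`, `family`, `PD`,
#'   `PS`, `aggregator`, `n_compounds`, with the rooted tree in attribute
#'   `tree`.
#' @export
run_scoring <- function(host, blends, genes = NULL, tree = NULL,
                        targets = isothiocyanate_targets(),
                        rooting = c("midpoint", "outgroup"), outgroup = NULL,
                        distance_model = "jc69",
                        aggregator = "mean_of_max", out_csv = NULL) {
  rooting <- match.arg(rooting)
  if (is.null(tree) && is.null(genes))
    stop("supply either gene alignments or a tree")
  if (!host %in% names(blends))
    stop(sprintf("host '%s' has no blend", host))
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.null(tree)) {
    aln <- concatenate_genes(genes)
    D <- pairwise_distance(aln, model = distance_model)
    tree <- build_nj_tree(D)
  }
  if (!host %in% tree$tip.label)
    stop(sprintf("host '%s' not in tree", host))
  if (!ape::is.rooted(tree))
    tree <- root_tree(tree, method = rooting, outgroup = outgroup)
  pd <- pd_table(tree, host)
  species <- sort(intersect(pd$taxon, names(blends)))
  missing_blend <- setdiff(pd$taxon, names(blends))
  if (length(missing_blend) > 0L)
    warning(sprintf("taxa without blends (PD only, dropped from table): %s",
                    paste(missing_blend, collapse = ", ")))
  tab <- data.frame(
    species = species,
    family = vapply(blends[species], function(b) b$family, ""),
    PD = pd$PD[match(species, pd$taxon)],
    PS = vapply(blends[species], blend_similarity, 0,
                targets = targets, aggregator = aggregator),
    aggregator = aggregator,
    n_compounds = vapply(blends[species], function(b) length(b$compounds), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_csv)) utils::write.csv(format_scores(tab), out_csv, row.names = FALSE)
  structure(tab, tree = tree, class = c("score_table", "data.frame"))
}

format_scores <- function(tab) {
  tab$PD <- sprintf("%.4f", tab$PD)
  tab$PS <- sprintf("%.4f", tab$PS)
  tab
}

#' Run every behavioral analysis against a score table
#'
#' The full analysis chain: week-block QC filter, treatment count model,
#' percent change from control, expected choice proportions, per-treatment
#' Hotelling choice tests and odds ratios, per-treatment exact olfactometer
#' tests, and the PD/PS predictor regressions (negative binomial and Poisson
#' on counts, logistic on olfactometer arm choices, linear R-squared fits on
#' percent change). With `exclude_phytotoxic = TRUE`, treatments flagged in
#' `phytotoxic` are dropped from every table before analysis (the
#' sensitivity re-analysis).
#'
#' @param scores A `score_table` (or data frame with `species`, `PD`, `PS`).
#' @param nochoice,choice,olfactometer Assay data frames (see the behavior
#'   functions for schemas); `olfactometer` may be empty or `NULL`.
#' @param phytotoxic Optional data frame `treatment`, `phytotoxic` (logical).
#' @param exclude_phytotoxic Drop flagged treatments everywhere.
#' @param min_control_mean QC threshold for week blocks.
#' @param count_family Family for the treatment count model.
#' @param out_dir Optional directory; writes one CSV per assay plus
#'   `regression_summary.csv` and `run_info.csv`.
#' @return List of class `behavior_results`: `qc`, `count_model`,
#'   `percent_change`, `choice_tests`, `olfactometer_tests`, `regressions`
#'   (list of `predictor_fit`), `regression_summary` (data frame), and
#'   `excluded_treatments`.
#' @export
run_behavior <- function(scores, nochoice, choice, olfactometer = NULL,
                         phytotoxic = NULL, exclude_phytotoxic = FALSE,
                         min_control_mean = 5, count_family = "negbin",
                         out_dir = NULL) {
  if (inherits(scores, "score_table") || "species" %in% names(scores)) {
    scores <- data.frame(treatment = scores$species, PD = scores$PD,
                         PS = scores$PS, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("treatment", "PD", "PS") %in% names(scores)))
  excluded <- character(0)
  if (exclude_phytotoxic) {
    if (is.null(phytotoxic)) stop("exclude_phytotoxic = TRUE needs the phytotoxic table")
    excluded <- phytotoxic$treatment[phytotoxic$phytotoxic]
    drop_rows <- function(df) df[!df$treatment %in% excluded, , drop = FALSE]
    nochoice <- drop_rows(nochoice)
    choice <- drop_rows(choice)
    if (!is.null(olfactometer) && nrow(olfactometer) > 0L)
      olfactometer <- drop_rows(olfactometer)
  }
  trts <- unique(c(setdiff(nochoice$treatment, CONTROL_LABEL),
                   choice$treatment,
                   if (!is.null(olfactometer)) olfactometer$treatment))
  unscored <- setdiff(trts, scores$treatment)
  if (length(unscored) > 0L)
    stop(sprintf("treatments missing from the score table: %s",
                 paste(unscored, collapse = ", ")))

  qc <- qc_filter_weeks(nochoice, min_control_mean = min_control_mean)
  if (nrow(qc$trials) == 0L) stop("QC filter removed every week block")
  cm <- fit_treatment_count_model(qc$trials, family = count_family)
  pc <- percent_change_from_control(qc$trials)

  choice_tests <- do.call(rbind, lapply(split(choice, choice$treatment), function(cg) {
    tr <- cg$treatment[1L]
    i <- match(tr, pc$treatment)
    p0 <- if (!is.na(i)) expected_choice_proportion(pc$mean_treated[i], pc$mean_control[i]) else 0.5
    ht <- hotelling_choice_test(cg, p0)
    or <- choice_odds_ratio(cg)
    data.frame(treatment = tr, n_cages = ht$n, p0 = p0,
               mean_fraction = ht$mean_fraction, T2 = ht$T2, F = ht$F,
               hotelling_p = ht$p_value,
               odds_ratio = or$odds_ratio, or_lower = or$lower,
               or_upper = or$upper, or_p = or$p_value,
               separation = or$separation,
               stringsAsFactors = FALSE)
  }))
  rownames(choice_tests) <- NULL

  olf_tests <- NULL
  if (!is.null(olfactometer) && nrow(olfactometer) > 0L) {
    olf_tests <- do.call(rbind, lapply(split(olfactometer, olfactometer$treatment),
                                       function(d) {
      res <- olfactometer_exact_test(d)
      data.frame(treatment = d$treatment[1L], chose_treated = res$k,
                 n_choices = res$n,
                 no_choice = res$tally[["no_choice"]],
                 stress = res$tally[["stress"]],
                 exact_p = res$p_value, stringsAsFactors = FALSE)
    }))
    rownames(olf_tests) <- NULL
  }

  # predictor regressions across treatments
  counts <- qc$trials[qc$trials$treatment != CONTROL_LABEL, , drop = FALSE]
  counts <- merge(counts, scores, by = "treatment")
  pc_sc <- merge(pc, scores, by = "treatment")
  regressions <- list(
    count_PD_negbin = predictor_regression(counts, "count", "PD", "negbin"),
    count_PD_poisson = predictor_regression(counts, "count", "PD", "poisson"),
    count_PS_poisson = predictor_regression(counts, "count", "PS", "poisson"),
    percent_change_PD_linear = predictor_regression(pc_sc, "percent_change", "PD", "linear"),
    percent_change_PS_linear = predictor_regression(pc_sc, "percent_change", "PS", "linear"))
  if (!is.null(olf_tests) && nrow(olf_tests) >= 3L) {
    olf_sc <- merge(olf_tests, scores, by = "treatment")
    olf_sc <- olf_sc[olf_sc$n_choices > 0, , drop = FALSE]
    if (length(unique(olf_sc$PD)) >= 3L)
      regressions$olf_PD_logistic <- predictor_regression(
        olf_sc, c("chose_treated", "n_choices"), "PD", "logistic")
    if (length(unique(olf_sc$PS)) >= 3L)
      regressions$olf_PS_logistic <- predictor_regression(
        olf_sc, c("chose_treated", "n_choices"), "PS", "logistic")
  }
  regression_summary <- do.call(rbind, lapply(names(regressions), function(nm) {
    f <- regressions[[nm]]
    sl <- f$coefficients[2L, ]
    data.frame(analysis = nm, family = f$family, slope = sl$estimate,
               se = sl$se, statistic = sl$statistic, p = sl$p,
               r_squared = f$r_squared, theta = f$theta,
               stringsAsFactors = FALSE)
  }))

  res <- structure(list(qc = qc, count_model = cm, percent_change = pc,
                        choice_tests = choice_tests,
                        olfactometer_tests = olf_tests,
                        regressions = regressions,
                        regression_summary = regression_summary,
                        excluded_treatments = excluded),
                   class = "behavior_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    w(qc$report, "qc_report.csv")
    w(cm$coefficients, "count_model.csv")
    w(pc, "percent_change.csv")
    w(choice_tests, "choice_tests.csv")
    w(olf_tests, "olfactometer_tests.csv")
    w(regression_summary, "regression_summary.csv")
    w(data.frame(package = "repelscore",
                 version = as.character(utils::packageVersion("repelscore")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 excluded_treatments = paste(excluded, collapse = ";")),
      "run_info.csv")
  }
  res
}

#' @export
print.behavior_results <- function(x, ...) {
  cat(sprintf("<behavior results> %d treatments, %d week blocks retained (%d dropped)\n",
              nrow(x$percent_change), sum(!x$qc$report$dropped),
              sum(x$qc$report$dropped)))
  cat("regression summary:\n")
  print(x$regression_summary, digits = 4)
  invisible(x)
}
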