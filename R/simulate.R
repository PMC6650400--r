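# Synthetic-data generator: trees and barcode sequences, volatile blends with
# known similarity structure, and behavioral datasets linked to the true
# PD/PS scores — so every pipeline stage can be tested against known
# ground-truth parameters without any external data.

# one global seed fans out to fixed per-stream child seeds so each stage can
# be re-run independently and deterministically
fan_seed <- function(seed, stream) {
  streams <- c(tree = 1L, sequences = 2L, chem = 3L, behavior = 4L,
               phytotoxic = 5L, misc = 6L)
  if (!stream %in% names(streams)) stop(sprintf("unknown seed stream '%s'", stream))
  as.integer((as.numeric(seed) * 7919 + streams[[stream]]) %% 2147483563)
}

#' Simulation configuration
#'
#' Bundles all generator parameters. Defaults mirror the emulated study
#' design: 19 taxa (one host plus 18 candidates), two barcode genes totalling
#' about 1.6 kb, blends of 8 compounds, 20 no-choice cages per treatment (10
#' treated + 5 control per week over two week blocks), 10 choice cages, and
#' 30 olfactometer replicates.
#'
#' @param seed Integer seed (mandatory); fans out to per-stream child seeds.
#' @param n_taxa Number of taxa including the host.
#' @param bl_mean Mean of the exponential branch-length distribution
#'   (substitutions/site).
#' @param genes Named integer vector of gene block lengths (sites).
#' @param n_missing_gene2 Number of non-host taxa missing the second gene
#'   (emulates a taxon represented by a single barcode gene).
#' @param compounds_per_blend Compounds per candidate volatile blend.
#' @param edit_range Integer range of structural edits applied when deriving
#'   candidate compounds from the host kairomones (more edits, lower PS).
#' @param beta0 Intercept of the no-choice count model: log mean larvae on
#'   control plants.
#' @param beta_pd,beta_ps Log-linear effects of PD and centered PS (PS - 1)
#'   on no-choice counts.
#' @param k Negative-binomial dispersion (variance `mu + mu^2/k`).
#' @param n_nochoice Treated no-choice cages per treatment (split over two
#'   week blocks, each with half the treated cages and `n_nochoice/4`
#'   controls).
#' @param n_choice Choice cages per treatment.
#' @param n_olf Olfactometer replicates per treatment.
#' @param olf_beta_pd,olf_beta_ps Logit-scale effects of PD and centered PS
#'   on the probability of choosing the treated arm (0 score difference gives
#'   a 50:50 split).
#' @param p_stress,p_no_choice Probabilities of the stress and no-choice
#'   olfactometer outcomes.
#' @param n_phytotoxic Number of candidate treatments flagged phytotoxic.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_taxa = 19L, bl_mean = 0.06,
                       genes = c(matK = 900L, rbcL = 700L),
                       n_missing_gene2 = 1L,
                       compounds_per_blend = 8L, edit_range = 0:8,
                       beta0 = 3, beta_pd = -4, beta_ps = 0, k = 2,
                       n_nochoice = 20L, n_choice = 10L, n_olf = 30L,
                       olf_beta_pd = 0, olf_beta_ps = -3,
                       p_stress = 0.2, p_no_choice = 0.1,
                       n_phytotoxic = 6L) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L,
            n_taxa >= 3L, bl_mean > 0, all(genes >= 1L),
            compounds_per_blend >= 1L, all(edit_range >= 0L),
            k > 0, n_nochoice >= 4L, n_choice >= 2L, n_olf >= 1L,
            p_stress >= 0, p_no_choice >= 0, p_stress + p_no_choice <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim config> seed %d: %d taxa, %d-site genes [%s], %d compounds/blend\n",
              x$seed, x$n_taxa, sum(x$genes),
              paste(names(x$genes), collapse = ", "), x$compounds_per_blend))
  invisible(x)
}

#' Perturb a molecule by random structural edits
#'
#' Applies `n_edits` random single-atom element substitutions (among C, N, O,
#' S, respecting valence) or single/double bond-order toggles. Edits never
#' disconnect the graph; aromatic atoms and bonds are left untouched.
#' Deterministic given `seed`.
#'
#' @param mol A `molecule`.
#' @param n_edits Number of edits (`0` returns an identical graph).
#' @param seed Integer seed.
#' @return A perturbed `molecule`.
#' @export
perturb_molecule <- function(mol, n_edits, seed) {
  stopifnot(n_edits >= 0L)
  set.seed(as.integer(seed %% 2147483563))
  valence <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  out <- mol
  for (e in seq_len(n_edits)) {
    done <- FALSE
    for (attempt in 1:100) {
      types <- atom_types(out)
      if (stats::runif(1) < 0.5) {
        # element substitution on a non-aromatic atom
        cand <- which(!out$atoms$aromatic)
        if (length(cand) == 0L) next
        i <- cand[sample.int(length(cand), 1L)]
        used <- types$degree[i] + types$pi[i]
        alts <- names(valence)[valence >= used & names(valence) != out$atoms$element[i]]
        if (length(alts) == 0L) next
        out$atoms$element[i] <- alts[sample.int(length(alts), 1L)]
        done <- TRUE
      } else {
        # toggle a non-aromatic bond between single and double
        cand <- which(out$bonds$order %in% c("1", "2"))
        if (length(cand) == 0L) next
        bi <- cand[sample.int(length(cand), 1L)]
        a <- out$bonds$a[bi]; b <- out$bonds$b[bi]
        if (out$bonds$order[bi] == "2") {
          out$bonds$order[bi] <- "1"
          done <- TRUE
        } else {
          used <- types$degree[c(a, b)] + types$pi[c(a, b)]
          cap <- valence[out$atoms$element[c(a, b)]]
          if (any(is.na(cap)) || any(used + 1L > cap)) next
          out$bonds$order[bi] <- "2"
          done <- TRUE
        }
      }
      if (done) break
    }
    if (!done) stop("molecule too constrained for the requested edit")
  }
  out$name <- if (n_edits > 0L) sprintf("%s~%d", mol$name, n_edits) else mol$name
  if (n_edits > 0L) out$smiles <- mol_to_smiles(out)
  out
}

# evolve a sequence matrix down a tree under JC69, site-independently
evolve_jc69 <- function(tree, sites) {
  bases <- c("A", "C", "G", "T")
  n_tip <- ape::Ntip(tree)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- sample(bases, sites, replace = TRUE)
  ord <- reorder(tree, "cladewise")  # parent always visited before child
  for (ei in seq_len(nrow(ord$edge))) {
    par <- ord$edge[ei, 1L]; child <- ord$edge[ei, 2L]
    b <- ord$edge.length[ei]
    p_change <- 0.75 * (1 - exp(-4 * b / 3))
    s <- seqs[[par]]
    hit <- stats::runif(sites) < p_change
    if (any(hit)) {
      # substitute uniformly among the three other bases
      cur <- s[hit]
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      s[hit] <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
    }
    seqs[[child]] <- s
  }
  tips <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(tips) <- tree$tip.label
  tips
}

#' Simulate a tree and barcode-gene alignments
#'
#' Draws a random rooted bifurcating topology with exponential branch
#' lengths, then evolves each gene site-independently under JC69 along it.
#' Optionally drops the second gene for some non-host taxa to emulate taxa
#' represented by a single barcode gene.
#'
#' @param config A `sim_config`.
#' @return List with `tree` (rooted `phylo`, tips `taxon_01`..., host =
#'   `taxon_01`), `genes` (list of `gene_alignment`), and `host`.
#' @export
simulate_tree_and_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(fan_seed(config$seed, "tree"))
  n <- config$n_taxa
  tree <- ape::rtree(n, rooted = TRUE,
                     br = function(nb) stats::rexp(nb, rate = 1 / config$bl_mean))
  tree$tip.label <- sprintf("taxon_%02d", seq_len(n))
  host <- "taxon_01"
  set.seed(fan_seed(config$seed, "sequences"))
  missing2 <- if (config$n_missing_gene2 > 0L && length(config$genes) >= 2L) {
    sample(setdiff(tree$tip.label, host), config$n_missing_gene2)
  } else character(0)
  genes <- lapply(seq_along(config$genes), function(gi) {
    seqs <- evolve_jc69(tree, config$genes[[gi]])
    if (gi == 2L && length(missing2) > 0L) seqs <- seqs[setdiff(names(seqs), missing2)]
    gene_alignment(names(config$genes)[gi], seqs)
  })
  list(tree = tree, genes = genes, host = host, missing_gene2 = missing2)
}

#' Simulate volatile blends with known similarity structure
#'
#' The host's blend is exactly the kairomone target set (so its PS is 1 by
#' construction); each candidate blend consists of compounds derived from
#' randomly chosen targets by a per-species number of structural edits drawn
#' from `edit_range` — more heavily edited blends are less similar to the
#' targets.
#'
#' @param config A `sim_config`.
#' @param taxa Character vector of taxa; the first is the host.
#' @param targets Target `blend` (defaults to the packaged isothiocyanates).
#' @return List with `blends` (named list of `blend`), `targets`, and
#'   `edits_per_species` (named vector, the similarity ground truth).
#' @export
simulate_blends <- function(config, taxa, targets = isothiocyanate_targets()) {
  stopifnot(inherits(config, "sim_config"), length(taxa) >= 2L)
  set.seed(fan_seed(config$seed, "chem"))
  host <- taxa[1L]
  host_blend <- targets
  host_blend$species <- host
  host_blend$family <- "family_host"
  edits <- stats::setNames(integer(length(taxa)), taxa)
  # spread candidate edit counts evenly over the range, then shuffle
  cand <- taxa[-1L]
  lv <- sort(rep_len(config$edit_range, length(cand)))
  edits[cand] <- sample(lv)
  blends <- c(list(host_blend), lapply(seq_along(cand), function(i) {
    sp <- cand[i]
    comps <- lapply(seq_len(config$compounds_per_blend), function(j) {
      base <- targets$compounds[[sample.int(length(targets$compounds), 1L)]]
      m <- perturb_molecule(base, edits[[sp]],
                            seed = fan_seed(config$seed, "chem") + i * 101L + j)
      m$name <- sprintf("%s_c%02d", sp, j)
      m
    })
    structure(list(species = sp, family = sprintf("family_%02d", (i %% 6L) + 1L),
                   compounds = comps),
              class = "blend")
  }))
  names(blends) <- taxa
  list(blends = blends, targets = targets, edits_per_species = edits)
}

#' Simulate behavioral datasets from true scores
#'
#' No-choice counts are negative binomial with
#' `log mu = beta0 + beta_pd * PD + beta_ps * (PS - 1)` for treated plants
#' and `log mu = beta0` for controls, in two week blocks per treatment.
#' Choice cages draw a Poisson total (expectation: two treated plus two
#' control plants at their no-choice means) allocated binomially by the
#' expected treated proportion `mu_t / (mu_t + mu_c)`. Olfactometer outcomes
#' are drawn from four categories: stress and no-choice at their configured
#' probabilities, the remainder choosing the treated arm with logistic
#' probability `plogis(olf_beta_pd * PD + olf_beta_ps * (PS - 1))`.
#'
#' @param scores Data frame with `treatment`, `PD`, `PS` (candidates only).
#' @param config A `sim_config`.
#' @return List of class `behavior_dataset` with `nochoice`, `choice`,
#'   `olfactometer` data frames and `truth` (per-treatment means and
#'   probabilities).
#' @export
simulate_behavior <- function(scores, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("treatment", "PD", "PS") %in% names(scores)),
            nrow(scores) >= 1L)
  set.seed(fan_seed(config$seed, "behavior"))
  mu_c <- exp(config$beta0)
  half <- config$n_nochoice %/% 2L
  n_ctrl_wk <- max(1L, config$n_nochoice %/% 4L)
  nochoice <- list(); choice <- list(); olf <- list(); truth <- list()
  for (r in seq_len(nrow(scores))) {
    tr <- scores$treatment[r]
    lp <- config$beta0 + config$beta_pd * scores$PD[r] +
      config$beta_ps * (scores$PS[r] - 1)
    mu_t <- exp(lp)
    p_choice <- mu_t / (mu_t + mu_c)
    p_arm <- stats::plogis(config$olf_beta_pd * scores$PD[r] +
                             config$olf_beta_ps * (scores$PS[r] - 1))
    for (wk in 1:2) {
      week <- sprintf("%s_wk%d", tr, wk)
      n_t <- if (wk == 1L) half else config$n_nochoice - half
      nochoice[[length(nochoice) + 1L]] <- data.frame(
        treatment = c(rep(tr, n_t), rep(CONTROL_LABEL, n_ctrl_wk)),
        week = week,
        cage = seq_len(n_t + n_ctrl_wk),
        count = c(stats::rnbinom(n_t, mu = mu_t, size = config$k),
                  stats::rnbinom(n_ctrl_wk, mu = mu_c, size = config$k)),
        stringsAsFactors = FALSE)
    }
    tot <- stats::rpois(config$n_choice, lambda = 2 * mu_t + 2 * mu_c)
    tre <- stats::rbinom(config$n_choice, tot, p_choice)
    choice[[length(choice) + 1L]] <- data.frame(
      treatment = tr, cage = seq_len(config$n_choice),
      treated_count = tre, control_count = tot - tre,
      stringsAsFactors = FALSE)
    u <- stats::runif(config$n_olf)
    outcome <- ifelse(u < config$p_stress, "stress",
               ifelse(u < config$p_stress + config$p_no_choice, "no_choice",
               ifelse(stats::runif(config$n_olf) < p_arm,
                      "chose_treated", "chose_control")))
    olf[[length(olf) + 1L]] <- data.frame(
      treatment = tr, replicate = seq_len(config$n_olf), outcome = outcome,
      stringsAsFactors = FALSE)
    truth[[tr]] <- list(mu_treated = mu_t, mu_control = mu_c,
                        p_choice = p_choice, p_arm = p_arm)
  }
  structure(list(nochoice = do.call(rbind, nochoice),
                 choice = do.call(rbind, choice),
                 olfactometer = do.call(rbind, olf),
                 truth = truth),
            class = "behavior_dataset")
}

#' @export
print.behavior_dataset <- function(x, ...) {
  cat(sprintf("<behavior dataset> %d no-choice rows, %d choice cages, %d olfactometer trials\n",
              nrow(x$nochoice), nrow(x$choice), nrow(x$olfactometer)))
  invisible(x)
}

#' Simulate a full study
#'
#' Runs the whole generator: tree and sequences, blends, true PD/PS score
#' table (computed from the true tree and the generated blends), behavioral
#' datasets linked to those scores, and phytotoxicity flags. Optionally
#' writes every dataset in the CSV/FASTA/Newick schemas the pipeline
#' consumes, plus `truth.json` with all generating parameters.
#'
#' @param config A `sim_config`.
#' @param dir Optional output directory (created if missing).
#' @return List with `config`, `tree`, `genes`, `host`, `blends`, `targets`,
#'   `scores` (true score table), `behavior`, `phytotoxic` (flag data frame),
#'   and `files` (paths written, if `dir` was given).
#' @export
simulate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  phy <- simulate_tree_and_sequences(config)
  chem <- simulate_blends(config, taxa = phy$tree$tip.label)
  targets_fp <- chem$targets
  pd <- pd_table(phy$tree, phy$host)
  scores <- data.frame(
    treatment = pd$taxon,
    family = vapply(chem$blends[pd$taxon], function(b) b$family, ""),
    PD = pd$PD,
    PS = vapply(chem$blends[pd$taxon], blend_similarity, 0, targets = targets_fp),
    row.names = NULL, stringsAsFactors = FALSE)
  cand <- scores[scores$treatment != phy$host, , drop = FALSE]
  behavior <- simulate_behavior(cand, config)
  set.seed(fan_seed(config$seed, "phytotoxic"))
  phyto <- data.frame(
    treatment = cand$treatment,
    phytotoxic = seq_len(nrow(cand)) %in%
      sample.int(nrow(cand), min(config$n_phytotoxic, nrow(cand))),
    stringsAsFactors = FALSE)
  out <- list(config = config, tree = phy$tree, genes = phy$genes,
              host = phy$host, missing_gene2 = phy$missing_gene2,
              blends = chem$blends, targets = chem$targets,
              edits_per_species = chem$edits_per_species,
              scores = scores, behavior = behavior, phytotoxic = phyto)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c()
    for (g in phy$genes)
      files[paste0("gene_", g$gene)] <-
        write_gene_fasta(g, file.path(dir, paste0(g$gene, ".fasta")))
    files["true_tree"] <- write_newick(phy$tree, file.path(dir, "true_tree.nwk"))
    files["blends"] <- write_blend_csv(chem$blends, file.path(dir, "blends.csv"))
    files["targets"] <- write_blend_csv(list(chem$targets), file.path(dir, "targets.csv"))
    for (tbl in c("nochoice", "choice", "olfactometer")) {
      p <- file.path(dir, paste0(tbl, ".csv"))
      utils::write.csv(behavior[[tbl]], p, row.names = FALSE)
      files[tbl] <- p
    }
    files["treatments"] <- file.path(dir, "treatments.csv")
    utils::write.csv(phyto, files[["treatments"]], row.names = FALSE)
    files["truth"] <- file.path(dir, "truth.json")
    truth <- list(
      seed = config$seed,
      behavior_params = config[c("beta0", "beta_pd", "beta_ps", "k",
                                 "olf_beta_pd", "olf_beta_ps",
                                 "p_stress", "p_no_choice")],
      host = phy$host,
      edits_per_species = as.list(chem$edits_per_species),
      true_scores = scores)
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, digits = NA)
    out$files <- files
  }
  out
}
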