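# Synthetic longitudinal cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: five community types (four dominated by Staphylococcus,
# Streptococcus, Moraxella and Corynebacterium, one mixed), time-varying
# type marginals with sticky Markov transitions, cohort-level genus
# trajectories (Staphylococcus 49/22/10%, Streptococcus 17/31/29%, Moraxella
# 9/13/23% at 1 week / 1 month / 3 months), per-subject persistent "core"
# OTUs carrying a configured share of reads, Dirichlet-multinomial count
# noise, log-normal sequencing depths and per-visit missingness.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g[alpha <= 0] <- 0
  s <- sum(g)
  if (s == 0) {
    g[which.max(alpha)] <- 1
    s <- 1
  }
  g / s
}

# Sticky transition matrix T = a*I + (1-a)*1q' with row sums 1, chosen so
# that p_from' T = p_to and sum_k p_from_k T_kk equals the target agreement.
make_sticky_transition <- function(p_from, p_to, agreement) {
  a <- (agreement - sum(p_from * p_to)) / (1 - sum(p_from^2))
  if (a < 0 || a >= 1)
    stop("agreement target infeasible for these marginals", call. = FALSE)
  q <- (p_to - a * p_from) / (1 - a)
  if (any(q < 0)) stop("agreement target infeasible (negative q)", call. = FALSE)
  Tm <- matrix(rep((1 - a) * q, each = length(q)), length(q))
  diag(Tm) <- diag(Tm) + a
  dimnames(Tm) <- list(names(p_from), names(p_from))
  Tm
}

# Base membership probabilities such that mixing over the sibling covariate
# reproduces the target marginal (fixed-point iteration, deterministic).
solve_base_probs <- function(target, beta, prev) {
  softmax <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  b <- target
  for (i in 1:200) {
    mix <- (1 - prev) * softmax(log(b)) + prev * softmax(log(b) + beta)
    b <- b * target / mix
    b <- b / sum(b)
  }
  b
}

#' Default synthetic-cohort configuration
#'
#' Ships a configuration whose expected cohort-level genus trajectories match
#' the observed hypopharyngeal succession (Staphylococcus 49/22/10%,
#' Streptococcus 17/31/29%, Moraxella 9/13/23% of reads at the three visits),
#' with five pneumotypes (Staphylococcus-, Streptococcus-, Moraxella- and
#' Corynebacterium-dominated plus one mixed type) at visit marginals taken
#' from the study's per-pneumotype sample counts, sticky transition matrices
#' reproducing the consecutive-visit agreement (28% and 34%), a sibling
#' covariate that shifts membership towards the Moraxella and mixed types,
#' per-subject core persistence shares of 0.90/0.81/0.63, and log-normal
#' sequencing depths of which about 5% fall below the 2000-read QC cut.
#'
#' @param n_subjects Number of subjects (default 300).
#' @param seed Integer seed stored in the config.
#' @return A `sim_config` list; fields may be modified before calling
#'   [generate_cohort()].
#' @export
default_config <- function(n_subjects = 300, seed = 1) {
  genera <- c("Staphylococcus", "Streptococcus", "Moraxella", "Corynebacterium",
              "Haemophilus", "Gemella", "Dolosigranulum", "Neisseria",
              "Prevotella", "Veillonella")
  phyla <- c(Staphylococcus = "Firmicutes", Streptococcus = "Firmicutes",
             Moraxella = "Proteobacteria", Corynebacterium = "Actinobacteria",
             Haemophilus = "Proteobacteria", Gemella = "Firmicutes",
             Dolosigranulum = "Firmicutes", Neisseria = "Proteobacteria",
             Prevotella = "Bacteroidetes", Veillonella = "Firmicutes")
  otus_per_genus <- 10L
  n_otus <- otus_per_genus * length(genera)
  otu_id <- paste0("OTU", seq_len(n_otus))
  genus_map <- stats::setNames(rep(genera, each = otus_per_genus), otu_id)

  types <- c("I", "II", "III", "IV", "V")
  dominant <- c(I = "Staphylococcus", II = "Streptococcus", III = "Moraxella",
                IV = "Corynebacterium", V = NA)
  tp <- timepoint_levels()
  marginals <- rbind(W1 = c(297, 87, 51, 24, 85) / 544,
                     M1 = c(137, 211, 89, 53, 131) / 621,
                     M3 = c(54, 196, 165, 30, 178) / 623)
  colnames(marginals) <- types
  # cohort-level genus share targets for the four dominant genera
  genus_targets <- rbind(W1 = c(0.49, 0.17, 0.09, 0.05),
                         M1 = c(0.22, 0.31, 0.13, 0.06),
                         M3 = c(0.10, 0.29, 0.23, 0.05))
  colnames(genus_targets) <- genera[1:4]
  background_weights <- c(Haemophilus = 0.25, Gemella = 0.20,
                          Dolosigranulum = 0.15, Neisseria = 0.15,
                          Prevotella = 0.15, Veillonella = 0.10)
  dominance <- 0.65

  # per-timepoint genus profiles: type k in I-IV puts `dominance` on its
  # genus plus (1 - dominance) of a background composition b_t; type V is
  # b_t itself. b_t is solved so the marginal mixture hits genus_targets.
  profiles <- list()
  for (t in tp) {
    p <- marginals[t, ]
    ct <- 1 - dominance + dominance * p[["V"]]
    b <- stats::setNames(numeric(length(genera)), genera)
    b[genera[1:4]] <- (genus_targets[t, ] - dominance * p[1:4]) / ct
    if (any(b < 0)) stop("genus targets infeasible at ", t, call. = FALSE)
    rest <- 1 - sum(b[genera[1:4]])
    b[names(background_weights)] <- rest * background_weights / sum(background_weights)
    prof <- matrix(0, length(types), length(genera),
                   dimnames = list(types, genera))
    for (k in types) {
      if (is.na(dominant[[k]])) prof[k, ] <- b
      else {
        prof[k, ] <- (1 - dominance) * b
        prof[k, dominant[[k]]] <- prof[k, dominant[[k]]] + dominance
      }
    }
    profiles[[t]] <- prof
  }

  agreement_targets <- c(W1_M1 = 0.28, M1_M3 = 0.34)
  transitions <- list(
    W1_M1 = make_sticky_transition(marginals["W1", ], marginals["M1", ],
                                   agreement_targets[["W1_M1"]]),
    M1_M3 = make_sticky_transition(marginals["M1", ], marginals["M3", ],
                                   agreement_targets[["M1_M3"]]))

  sibling_beta <- c(I = -0.5, II = 0, III = 0.8, IV = 0, V = 0.8)
  covariates <- list(siblings = 0.56, csection = 0.22, mother_asthma = 0.26,
                     male = 0.51,
                     antibiotics = c(W1 = 0.02, M1 = 0.04, M3 = 0.05),
                     exclusively_breastfed = c(W1 = 0.88, M1 = 0.76, M3 = 0.63),
                     sibling_beta = sibling_beta)
  base_probs <- solve_base_probs(marginals["W1", ], sibling_beta,
                                 covariates$siblings)

  cfg <- list(
    n_subjects = n_subjects,
    timepoints = tp,
    genera = genera,
    phyla = phyla,
    otus_per_genus = otus_per_genus,
    genus_map = genus_map,
    pneumotypes = types,
    dominant_genus = dominant,
    dominance = dominance,
    marginals = marginals,
    genus_targets = genus_targets,
    profiles = profiles,
    initial_probs = base_probs,
    transitions = transitions,
    covariates = covariates,
    dirichlet_concentration = 1000,
    alloc_alpha_persistent = c(2.8, rep(0.3, 6), rep(0.02, 3)),
    alloc_alpha_transient = rep(0.08, 10),
    persist_support = 0.08,           # pi above this marks an OTU persistent
    core_share = c(W1 = 0.90, M1 = 0.81, M3 = 0.63),
    core_detect_threshold = 0.0025,   # expected rarefied count >= 5 at depth 2000
    depth_meanlog = 9.25,
    depth_sdlog = 1.0,
    depth_floor = 500,
    missingness = 0.14,
    tree_within_genus_scale = 0.5,
    store_compositions = FALSE,
    seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param config A `sim_config` list.
#' @return The config, invisibly error otherwise.
#' @export
validate_sim_config <- function(config) {
  ok1 <- function(x) abs(sum(x) - 1) < 1e-9 && all(x >= 0)
  if (!all(apply(config$marginals, 1L, ok1)))
    stop("marginals rows must be probability vectors", call. = FALSE)
  for (t in names(config$profiles))
    if (!all(apply(config$profiles[[t]], 1L, ok1)))
      stop("profiles at ", t, " must be probability vectors", call. = FALSE)
  for (nm in names(config$transitions))
    if (!all(abs(rowSums(config$transitions[[nm]]) - 1) < 1e-9))
      stop("transition matrix ", nm, " rows must sum to 1", call. = FALSE)
  if (!ok1(config$initial_probs))
    stop("initial_probs must be a probability vector", call. = FALSE)
  if (config$dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be > 0", call. = FALSE)
  if (!setequal(unique(config$genus_map), config$genera))
    stop("inconsistent genus/OTU map", call. = FALSE)
  if (any(config$core_share <= 0 | config$core_share >= 1))
    stop("core_share must be in (0,1)", call. = FALSE)
  invisible(config)
}

#' Random genus-structured phylogeny over the OTUs
#'
#' A near-star backbone over genera (deep inter-genus splits collapsed to
#' negligible internal branches, as is typical for short 16S fragments, but
#' kept binary so the tree is rooted) with random exponential genus branch
#' lengths, and small random coalescent subtrees grafted at each genus tip.
#' Within-genus tip-to-tip distances are therefore much shorter than
#' between-genus distances, and no pair of genera is artificially closer
#' than another, so phylogenetic distance correlates with taxonomy.
#'
#' @param n_otus Number of tips (>= 2); ignored when `genus_map` is given
#'   (then a plain random coalescent tree is returned).
#' @param seed Integer seed.
#' @param genus_map Optional named character vector OTU id -> genus.
#' @param within_scale Branch-length scale of the within-genus subtrees
#'   relative to the backbone.
#' @return A rooted `phylo` object with OTU-id tip labels.
#' @export
generate_tree <- function(n_otus = 100, seed = 1, genus_map = NULL,
                          within_scale = 0.15) {
  set.seed(seed)
  if (is.null(genus_map)) {
    stopifnot(n_otus >= 2)
    return(ape::rcoal(n_otus, tip.label = paste0("OTU", seq_len(n_otus))))
  }
  genera <- unique(genus_map)
  tree <- if (length(genera) >= 2) {
    bl <- 0.8 + stats::rexp(length(genera), rate = 2)
    nest <- sprintf("(%s:%.6f,%s:%.6f)", genera[1L], bl[1L], genera[2L], bl[2L])
    for (gi in seq_along(genera)[-(1:2)])
      nest <- sprintf("(%s:0.000001,%s:%.6f)", nest, genera[gi], bl[gi])
    ape::read.tree(text = paste0(nest, ";"))
  } else NULL
  for (g in genera) {
    otus <- names(genus_map)[genus_map == g]
    sub <- if (length(otus) >= 2) {
      s <- ape::rcoal(length(otus), tip.label = otus)
      s$edge.length <- s$edge.length * within_scale
      s
    } else NULL
    if (is.null(tree)) return(sub)
    if (is.null(sub)) {
      tree$tip.label[tree$tip.label == g] <- otus
    } else {
      tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == g))
    }
  }
  tree
}

#' Generate a synthetic longitudinal cohort
#'
#' Per subject: draws covariates; draws the 1-week pneumotype from
#' sibling-adjusted membership logits and propagates it through the sticky
#' transition matrices; draws once per genus a persistent within-genus OTU
#' allocation (the subject's core strains). Per emitted sample: blends the
#' persistent and a fresh transient allocation at the time-point's core
#' share, scales by the pneumotype's genus profile, applies
#' Dirichlet-multinomial noise at the configured concentration, draws a
#' log-normal read depth and multinomial counts, and applies per-visit
#' missingness. Fully deterministic given `config$seed`.
#'
#' @param config A `sim_config` (see [default_config()]).
#' @return A `synthetic_cohort` list: `table` ([otu_table()] with taxonomy),
#'   `tree`, `metadata`, and `truth` (per-sample planted pneumotype, planted
#'   per-subject core OTU sets, planted dominant indicator OTUs, and the
#'   config).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  tp <- config$timepoints
  types <- config$pneumotypes
  genera <- config$genera
  otu_id <- names(config$genus_map)
  n_otus <- length(otu_id)
  theta <- config$dirichlet_concentration
  softmax <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))

  n <- config$n_subjects
  subj <- sprintf("S%04d", seq_len(n))
  siblings <- stats::runif(n) < config$covariates$siblings
  csection <- stats::runif(n) < config$covariates$csection
  mother_asthma <- stats::runif(n) < config$covariates$mother_asthma
  sex <- ifelse(stats::runif(n) < config$covariates$male, "male", "female")
  birth_month <- sample.int(12L, n, replace = TRUE)

  # pneumotype path
  beta <- config$covariates$sibling_beta
  k1 <- vapply(seq_len(n), function(i) {
    p <- if (siblings[i]) softmax(log(config$initial_probs) + beta)
         else softmax(log(config$initial_probs))
    sample.int(length(types), 1L, prob = p)
  }, integer(1))
  k2 <- vapply(k1, function(k)
    sample.int(length(types), 1L, prob = config$transitions$W1_M1[k, ]), integer(1))
  k3 <- vapply(k2, function(k)
    sample.int(length(types), 1L, prob = config$transitions$M1_M3[k, ]), integer(1))
  path <- cbind(W1 = k1, M1 = k2, M3 = k3)

  # per-subject persistent within-genus allocations (core strains)
  ap <- config$alloc_alpha_persistent
  at <- config$alloc_alpha_transient
  genus_idx <- lapply(genera, function(g) which(config$genus_map == g))
  names(genus_idx) <- genera
  persist <- lapply(seq_len(n), function(i) {
    al <- numeric(n_otus)
    for (g in genera) {
      idx <- genus_idx[[g]]
      al[idx] <- rdirichlet1(rep_len(ap, length(idx)))
    }
    al
  })
  # transient draws avoid each subject's persistent-support OTUs and rotate
  # through visit-specific pools of the remaining OTUs, so the transient
  # fraction turns over instead of re-hitting the same strains
  support <- lapply(persist, function(al) al >= config$persist_support)
  pools <- lapply(seq_len(n), function(i) {
    pool <- integer(n_otus)
    for (g in genera) {
      idx <- genus_idx[[g]]
      nonsup <- idx[!support[[i]][idx]]
      if (length(nonsup))
        pool[nonsup] <- sample(rep_len(seq_along(tp), length(nonsup)))
    }
    pool
  })

  present <- matrix(stats::runif(n * length(tp)) >= config$missingness, n,
                    dimnames = list(subj, tp))
  ages_mu <- c(W1 = 8, M1 = 32, M3 = 93)
  ages_sd <- c(W1 = 3, M1 = 5, M3 = 6)

  counts <- list()
  meta <- list()
  truth_rows <- list()
  comps <- list()
  lam <- config$core_share
  for (i in seq_len(n)) {
    for (t in tp) {
      if (!present[i, t]) next
      k <- path[i, t]
      prof <- config$profiles[[t]][k, ]
      alloc <- numeric(n_otus)
      t_i <- match(t, tp)
      for (g in genera) {
        idx <- genus_idx[[g]]
        a_tr <- rep_len(at, length(idx))
        a_tr[pools[[i]][idx] != t_i] <- 0
        if (all(a_tr == 0)) a_tr <- rep_len(at, length(idx))
        tau <- rdirichlet1(a_tr)
        alloc[idx] <- lam[[t]] * persist[[i]][idx] + (1 - lam[[t]]) * tau
      }
      comp <- alloc * prof[config$genus_map]
      comp <- comp / sum(comp)
      x <- if (is.finite(theta)) rdirichlet1(theta * comp) else comp
      depth <- max(config$depth_floor,
                   round(stats::rlnorm(1, config$depth_meanlog, config$depth_sdlog)))
      cnt <- as.integer(stats::rmultinom(1L, depth, x))
      sid <- paste0(subj[i], "_", t)
      counts[[sid]] <- cnt
      if (config$store_compositions) comps[[sid]] <- rbind(mean = comp, drawn = x)
      meta[[sid]] <- data.frame(
        sample_id = sid, subject_id = subj[i], timepoint = t,
        age_days = max(1L, round(stats::rnorm(1, ages_mu[[t]], ages_sd[[t]]))),
        sex = sex[i], siblings = siblings[i], csection = csection[i],
        antibiotics = stats::runif(1) < config$covariates$antibiotics[[t]],
        exclusively_breastfed = stats::runif(1) < config$covariates$exclusively_breastfed[[t]],
        mother_asthma = mother_asthma[i], birth_month = birth_month[i],
        dna_conc = stats::rlnorm(1, log(0.8), 1.2),
        stringsAsFactors = FALSE)
      truth_rows[[sid]] <- data.frame(sample_id = sid, subject_id = subj[i],
                                      timepoint = t, label = types[k],
                                      stringsAsFactors = FALSE)
    }
  }
  cnt_mat <- do.call(rbind, counts)
  dimnames(cnt_mat) <- list(names(counts), otu_id)
  taxonomy <- parse_lineage(stats::setNames(
    paste("Bacteria", config$phyla[config$genus_map], "", "", "",
          config$genus_map, sep = ";"), otu_id))

  # planted core: OTUs whose persistent expected share clears the detection
  # threshold at every time-point actually sampled
  core_sets <- lapply(seq_len(n), function(i) {
    ts <- tp[present[i, ]]
    if (length(ts) == 0L) return(character(0))
    keep <- support[[i]]
    for (t in ts) {
      prof <- config$profiles[[t]][path[i, t], ]
      expab <- lam[[t]] * persist[[i]] * prof[config$genus_map]
      keep <- keep & (expab >= config$core_detect_threshold)
    }
    otu_id[keep]
  })
  names(core_sets) <- subj
  dom <- config$dominant_genus[!is.na(config$dominant_genus)]
  dominant_otus <- vapply(dom, function(g) otu_id[genus_idx[[g]][1L]], character(1))

  tree <- generate_tree(seed = config$seed + 1L, genus_map = config$genus_map,
                        within_scale = config$tree_within_genus_scale)
  structure(list(
    table = otu_table(cnt_mat, taxonomy = taxonomy),
    tree = tree,
    metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
    truth = list(pneumotype = do.call(rbind, c(truth_rows, make.row.names = FALSE)),
                 core_sets = core_sets,
                 dominant_otus = dominant_otus,
                 path = matrix(types[path], n, dimnames = list(subj, tp)),
                 compositions = if (config$store_compositions) comps,
                 config = config)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples from %d subjects, %d OTUs\n",
              n_samples(x$table), length(unique(x$metadata$subject_id)),
              n_otus(x$table)))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits counts TSV, taxonomy TSV, newick tree, metadata TSV and a truth
#' JSON into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(cohort$table, file.path(dir, "counts.tsv"))
  tax <- cohort$table$taxonomy
  utils::write.table(
    data.frame(otu_id = rownames(tax),
               lineage = apply(tax, 1L, paste, collapse = ";")),
    file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(pneumotype = cohort$truth$pneumotype,
                            core_sets = cohort$truth$core_sets,
                            dominant_otus = as.list(cohort$truth$dominant_otus)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
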