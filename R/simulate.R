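#' Simulator configuration
#'
#' Bundles every parameter of the synthetic-data generator with a master
#' seed, so one object fully determines a dataset.  Defaults describe the
#' study conditions the analysis modules are built for: a moderately sized
#' clade (64 tips) from a pure-birth process, a heritable three-level iron
#' environment evolving by slow nearest-neighbor transitions (habitat is
#' phylogenetically conserved, so clades are confounded with environment),
#' a slowly gained/lost gene whose loss rate rises with iron availability
#' (stationary carriage `logit^-1(intercept + slope * iron)`, default
#' slope -2), and a small ocean-survey-like metagenome panel (40 sites)
#' with realistic gene lengths and ~50 expected core-gene hits per site.
#' Faster `trait_rate_scale` / `env_rates` values describe a regime where
#' the gene tracks the current environment closely; see the package
#' vignette for how the two regimes are used.
#'
#' @param seed Master seed (integer).
#' @param n_tips Number of extant tips.
#' @param birth_rate,death_rate Birth-death rates per unit time;
#'   `birth_rate > death_rate >= 0`.
#' @param env_rates 3x3 transition-rate matrix for the iron level (rows sum
#'   to 0, off-diagonals non-negative).  Default: nearest-neighbor
#'   transitions at rate 0.3.
#' @param trait_intercept,trait_slope Logit-scale intercept and slope of the
#'   stationary carriage probability versus iron level.
#' @param trait_rate_scale Overall speed of trait gain/loss (per unit branch
#'   length); larger means weaker phylogenetic signal in the trait.
#' @param root_env,root_trait Optional fixed root states; by default the
#'   environment is drawn uniformly and the trait from its stationary
#'   distribution given the root environment.
#' @param metagenome Named list overriding any of: `n_sites`, `iron_range`,
#'   `carriage_intercept`, `carriage_slope`, `gene_lengths_kb` (named,
#'   target first), `target`, `cores`, `expected_core_hits`, `depth_sdlog`,
#'   `taxon`.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_tips = 64L,
                       birth_rate = 1, death_rate = 0,
                       env_rates = default_env_rates(),
                       trait_intercept = 2, trait_slope = -2,
                       trait_rate_scale = 0.15,
                       root_env = NULL, root_trait = NULL,
                       metagenome = list()) {
  meta <- utils::modifyList(list(
    n_sites = 40L, iron_range = c(0, 1),
    carriage_intercept = 2, carriage_slope = -4,
    gene_lengths_kb = c(fld = 0.5, recA = 1.1, rpoB = 4.1,
                        gyrB = 2.4, psbO = 0.8),
    target = "fld", cores = c("recA", "rpoB", "gyrB", "psbO"),
    expected_core_hits = 50, depth_sdlog = 0.5, taxon = "sim"),
    metagenome)
  cfg <- list(seed = as.integer(seed), n_tips = as.integer(n_tips),
              birth_rate = birth_rate, death_rate = death_rate,
              env_rates = env_rates,
              trait_intercept = trait_intercept,
              trait_slope = trait_slope,
              trait_rate_scale = trait_rate_scale,
              root_env = root_env, root_trait = root_trait,
              metagenome = meta)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param rate Nearest-neighbor transition rate between adjacent iron
#'   levels.
#' @export
default_env_rates <- function(rate = 0.15) {
  q <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  q[1, 2] <- q[2, 1] <- q[2, 3] <- q[3, 2] <- rate
  diag(q) <- -rowSums(q)
  q
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_tips >= 3, cfg$birth_rate > cfg$death_rate,
            cfg$death_rate >= 0)
  validate_rate_matrix(cfg$env_rates, 3L)
  m <- cfg$metagenome
  if (any(m$gene_lengths_kb <= 0)) stop("gene lengths must be positive")
  if (m$expected_core_hits < 0) stop("negative expected core hits")
  if (!all(c(m$target, m$cores) %in% names(m$gene_lengths_kb)))
    stop("gene_lengths_kb must name the target and every core gene")
  if (!all(is.finite(c(m$carriage_intercept, m$carriage_slope))))
    stop("invalid logistic carriage parameters")
  invisible(cfg)
}

validate_rate_matrix <- function(Q, k) {
  if (!is.matrix(Q) || any(dim(Q) != k))
    stop("rate matrix must be ", k, "x", k)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("negative off-diagonal rate")
  if (any(abs(rowSums(Q)) > 1e-8))
    stop("non-conservative rate matrix: rows must sum to 0")
  invisible(Q)
}

#' Trait gain/loss rates from a logistic stationary carriage curve
#'
#' Returns per-environment gain and loss rates whose stationary presence
#' probability is `logit^-1(intercept + slope * e)` for environment
#' `e = 0, 1, 2`, with overall switching speed `rate_scale` (the geometric
#' mean of gain and loss).  A negative slope makes the loss rate increase
#' with the environment level.
#'
#' @param intercept,slope Logit-scale parameters.
#' @param rate_scale Positive speed parameter.
#' @return List with numeric length-3 vectors `gain` and `loss`.
#' @export
trait_rates_logistic <- function(intercept, slope, rate_scale = 0.5) {
  stopifnot(rate_scale > 0)
  e <- 0:2
  half <- (intercept + slope * e) / 2
  list(gain = rate_scale * exp(half), loss = rate_scale * exp(-half))
}

#' Simulate a birth-death tree conditioned on the number of tips
#'
#' Forward (Gillespie) simulation starting from the two daughters of the
#' root: while `k` lineages are extant the next event arrives after an
#' exponential time with rate `k * (birth + death)`; a uniformly chosen
#' lineage then speciates or dies.  When the extant count first reaches
#' `n_tips` one further exponential holding time at `n_tips` lineages is
#' appended and all surviving lineages are cut there, so a pure-birth tree
#' has expected root-to-tip height `(1/birth) * sum_{k=2}^{n} 1/k`.
#' Extinct lineages are pruned from the returned tree.  Runs where the
#' whole clade dies are retried.
#'
#' @param n_tips Number of extant tips (>= 3 for downstream use; >= 2
#'   accepted here).
#' @param birth_rate,death_rate Event rates; `birth_rate > death_rate >= 0`.
#' @param seed Optional integer seed.
#' @param max_retries Retries allowed when the clade goes extinct.
#' @return A `"phylo"` tree with tips `t1 ... tn`.
#' @examples
#' tr <- simulate_tree(8, seed = 42)
#' tr$Nnode  # 7 internal nodes for 8 tips
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, death_rate = 0,
                          seed = NULL, max_retries = 100L) {
  stopifnot(n_tips >= 2, birth_rate > death_rate, death_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    tr <- .sim_bd_once(n_tips, birth_rate, death_rate)
    if (!is.null(tr)) return(validate_phylogeny(tr))
  }
  stop("birth-death simulation failed: clade went extinct in all ",
       max_retries, " attempts")
}

.sim_bd_once <- function(n, birth, death) {
  # active lineages: parent node id, birth time
  alive_parent <- c("n0", "n0"); alive_t0 <- c(0, 0)
  edges <- list(); n_int <- 0L; n_dead <- 0L
  t <- 0
  repeat {
    k <- length(alive_parent)
    if (k == 0L) return(NULL)
    if (k == n) {
      t_end <- t + stats::rexp(1, n * (birth + death))
      for (i in seq_len(n))
        edges[[length(edges) + 1L]] <-
          list(parent = alive_parent[i], child = paste0("t", i),
               len = t_end - alive_t0[i], tip = TRUE)
      break
    }
    t <- t + stats::rexp(1, k * (birth + death))
    i <- sample.int(k, 1L)
    if (stats::runif(1) < birth / (birth + death)) {
      n_int <- n_int + 1L
      id <- paste0("n", n_int)
      edges[[length(edges) + 1L]] <-
        list(parent = alive_parent[i], child = id,
             len = t - alive_t0[i], tip = FALSE)
      alive_parent <- c(alive_parent[-i], id, id)
      alive_t0 <- c(alive_t0[-i], t, t)
    } else {
      n_dead <- n_dead + 1L
      edges[[length(edges) + 1L]] <-
        list(parent = alive_parent[i], child = paste0("x", n_dead),
             len = t - alive_t0[i], tip = TRUE)
      alive_parent <- alive_parent[-i]
      alive_t0 <- alive_t0[-i]
    }
  }
  .edges_to_phylo(edges, n)
}

.edges_to_phylo <- function(edges, n_extant) {
  parent <- vapply(edges, `[[`, "", "parent")
  child <- vapply(edges, `[[`, "", "child")
  len <- vapply(edges, `[[`, 0, "len")
  is_tip <- vapply(edges, `[[`, TRUE, "tip")
  tips <- child[is_tip]
  internals <- c("n0", setdiff(unique(parent), c("n0")))
  idx <- c(stats::setNames(seq_along(tips), tips),
           stats::setNames(length(tips) + seq_along(internals), internals))
  tree <- structure(list(
    edge = cbind(unname(idx[parent]), unname(idx[child])),
    edge.length = len,
    tip.label = tips,
    Nnode = length(internals)), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  extinct <- grep("^x", tree$tip.label, value = TRUE)
  if (length(extinct)) tree <- ape::drop.tip(tree, extinct)
  if (is.null(tree) || length(tree$tip.label) != n_extant) return(NULL)
  tree
}

#' Simulate joint environment and trait evolution along a tree
#'
#' Evolves a six-state continuous-time Markov chain — the product of the
#' iron level (0/1/2) and the binary gene state — along every branch by
#' exact event-time (Gillespie) sampling.  Environment transitions follow
#' `env_rates`; the gene is gained at rate `gain[e]` and lost at rate
#' `loss[e]` given the current environment `e`, so trait and environment
#' are phylogenetically heritable and mutually coupled, reproducing the
#' confounding that motivates a phylogenetically corrected test.
#'
#' @param tree A `"phylo"` tree.
#' @param env_rates 3x3 conservative rate matrix.
#' @param gain,loss Length-3 non-negative rate vectors indexed by
#'   environment level (see [trait_rates_logistic()]).
#' @param root_env Root iron level in `0:2`, or `NULL` to draw uniformly.
#' @param root_trait `"present"`/`"absent"`, or `NULL` to draw from the
#'   stationary distribution given the root environment.
#' @param seed Optional integer seed.
#' @return List with `traits` (a `"trait_table"`, all genomes complete,
#'   `habitat = "env<e>"`, `iron_level = e`) and `truth` (root states,
#'   per-tip latent states, event count, parameters).
#' @export
simulate_env_trait <- function(tree, env_rates = default_env_rates(),
                               gain, loss,
                               root_env = NULL, root_trait = NULL,
                               seed = NULL) {
  tree <- validate_phylogeny(tree)
  validate_rate_matrix(env_rates, 3L)
  stopifnot(length(gain) == 3, length(loss) == 3,
            all(gain >= 0), all(loss >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root_env)) root_env <- sample(0:2, 1L)
  stopifnot(root_env %in% 0:2)
  if (is.null(root_trait)) {
    tot <- gain[root_env + 1] + loss[root_env + 1]
    p1 <- if (tot > 0) gain[root_env + 1] / tot else 0.5
    root_trait <- if (stats::runif(1) < p1) "present" else "absent"
  }
  stopifnot(root_trait %in% c("present", "absent"))

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  n_node <- n_tip + tree$Nnode
  env_state <- integer(n_node); trait_state <- integer(n_node)
  env_state[root] <- root_env
  trait_state[root] <- as.integer(root_trait == "present")
  n_events <- 0L
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
    st <- c(env_state[from], trait_state[from])
    remaining <- ord$edge.length[e]
    repeat {
      ev <- st[1L]; tr <- st[2L]
      r_env <- -env_rates[ev + 1L, ev + 1L]
      r_tr <- if (tr == 0L) gain[ev + 1L] else loss[ev + 1L]
      total <- r_env + r_tr
      if (total <= 0) break
      dt <- stats::rexp(1, total)
      if (dt > remaining) break
      remaining <- remaining - dt
      n_events <- n_events + 1L
      if (stats::runif(1) < r_tr / total) {
        st[2L] <- 1L - tr
      } else {
        rates <- env_rates[ev + 1L, ]; rates[ev + 1L] <- 0
        st[1L] <- sample(0:2, 1L, prob = rates)
      }
    }
    env_state[to] <- st[1L]; trait_state[to] <- st[2L]
  }
  tip_env <- env_state[seq_len(n_tip)]
  tip_trait <- trait_state[seq_len(n_tip)]
  traits <- trait_table(
    tree$tip.label,
    ifelse(tip_trait == 1L, "present", "absent"),
    genome_complete = TRUE,
    habitat = paste0("env", tip_env),
    iron_level = tip_env,
    provenance = list(simulated = TRUE))
  truth <- list(root_env = root_env, root_trait = root_trait,
                tip_env = stats::setNames(tip_env, tree$tip.label),
                tip_trait = stats::setNames(tip_trait, tree$tip.label),
                n_events = n_events,
                params = list(env_rates = env_rates, gain = gain,
                              loss = loss))
  list(traits = traits, truth = truth)
}

#' Simulate per-site metagenomic hit counts
#'
#' For each site, predicted iron is drawn uniformly on `iron_range`, the
#' true carriage fraction is `logit^-1(a + b * iron)`, and a per-site
#' sequencing depth multiplier is drawn log-normally (mean 1, spread
#' `depth_sdlog`).  Single-copy core gene `g` then receives
#' `Poisson(depth * L_g)` hits and the target gene
#' `Poisson(depth * L_target * carriage)` hits, with `L` in kb — the
#' generative model under which [gene_frequency()] is a consistent
#' carriage estimator.
#'
#' @param n_sites Number of sites.
#' @param iron_range Length-2 range for the uniform iron draw.
#' @param carriage_intercept,carriage_slope Logistic parameters `a`, `b`.
#' @param gene_lengths_kb Named positive vector covering target and cores.
#' @param target,cores Gene names.
#' @param expected_core_hits Expected hits for a core gene of average
#'   length at depth multiplier 1; 0 gives all-zero counts (degenerate
#'   sites, excluded downstream).
#' @param depth_sdlog Log-normal sd of the per-site depth multiplier.
#' @param taxon Taxon bin label stored on every row.
#' @param seed Optional integer seed.
#' @return Long site `data.frame` (see [read_site_table()]) with a `truth`
#'   attribute (per-site iron, carriage, depth).
#' @export
simulate_metagenome <- function(n_sites = 40L, iron_range = c(0, 1),
                                carriage_intercept = 2,
                                carriage_slope = -4,
                                gene_lengths_kb = c(fld = 0.5, recA = 1.1,
                                                    rpoB = 4.1, gyrB = 2.4,
                                                    psbO = 0.8),
                                target = "fld",
                                cores = c("recA", "rpoB", "gyrB", "psbO"),
                                expected_core_hits = 50,
                                depth_sdlog = 0.5,
                                taxon = "sim", seed = NULL) {
  stopifnot(n_sites >= 1, all(gene_lengths_kb > 0),
            expected_core_hits >= 0, depth_sdlog >= 0)
  if (!all(is.finite(c(carriage_intercept, carriage_slope))))
    stop("invalid logistic carriage parameters")
  if (!all(c(target, cores) %in% names(gene_lengths_kb)))
    stop("gene_lengths_kb must name the target and every core gene")
  if (!is.null(seed)) set.seed(seed)
  iron <- stats::runif(n_sites, iron_range[1], iron_range[2])
  carriage <- stats::plogis(carriage_intercept + carriage_slope * iron)
  mult <- if (depth_sdlog > 0)
    stats::rlnorm(n_sites, -depth_sdlog^2 / 2, depth_sdlog)
  else rep(1, n_sites)
  depth <- expected_core_hits / mean(gene_lengths_kb[cores]) * mult
  site_ids <- sprintf("S%03d", seq_len(n_sites))
  genes <- c(target, cores)
  rows <- expand.grid(site = seq_len(n_sites), gene = genes,
                      stringsAsFactors = FALSE)
  lam <- depth[rows$site] * gene_lengths_kb[rows$gene] *
    ifelse(rows$gene == target, carriage[rows$site], 1)
  out <- data.frame(site_id = site_ids[rows$site],
                    taxon = taxon,
                    gene = rows$gene,
                    hits = stats::rpois(nrow(rows), lam),
                    mean_query_length_kb =
                      unname(gene_lengths_kb[rows$gene]),
                    iron = iron[rows$site],
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(site_id = site_ids, iron = iron,
                                   carriage = carriage, depth = depth)
  out
}

#' Simulate a complete dataset from one configuration
#'
#' Runs [simulate_tree()], [simulate_env_trait()] and
#' [simulate_metagenome()] with per-stage seeds derived deterministically
#' from the master seed, so the whole dataset is reproducible from the
#' `"sim_config"` alone.
#'
#' @param config A `"sim_config"`.
#' @return List of class `"simulated_dataset"` with `tree`, `traits`,
#'   `truth`, `sites`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  seeds <- (config$seed + c(1L, 2L, 3L) * 1000003L) %% 2147483629L
  tree <- simulate_tree(config$n_tips, config$birth_rate,
                        config$death_rate, seed = seeds[1])
  rates <- trait_rates_logistic(config$trait_intercept, config$trait_slope,
                                config$trait_rate_scale)
  et <- simulate_env_trait(tree, config$env_rates, rates$gain, rates$loss,
                           root_env = config$root_env,
                           root_trait = config$root_trait,
                           seed = seeds[2])
  m <- config$metagenome
  sites <- simulate_metagenome(m$n_sites, m$iron_range,
                               m$carriage_intercept, m$carriage_slope,
                               m$gene_lengths_kb, m$target, m$cores,
                               m$expected_core_hits, m$depth_sdlog,
                               m$taxon, seed = seeds[3])
  structure(list(tree = tree, traits = et$traits, truth = et$truth,
                 sites = sites, config = config),
            class = "simulated_dataset")
}
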