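#' Parameters of the gene-family history simulator
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 30-species Yule tree, duplication rate 0.3 and loss rate 0.2 per
#' gene per unit branch length, rate episodes (multiplier 10 on the
#' duplication rate) on 20% of the branches, and an NNI perturbation
#' probability of 0.1 per internal edge for the topology-noise stage.
#'
#' @param n_species Number of species in the simulated species tree.
#' @param lambda Duplication rate per gene lineage per unit branch length.
#' @param mu Loss rate per gene lineage per unit branch length.
#' @param episode_fraction Fraction of species-tree branches with elevated
#'   rates.
#' @param rho Episode rate multiplier (>= 1).
#' @param episode_mode Which rate the episodes elevate: `"paired"` (the
#'   default: the duplication rate on the episode branches and the loss rate
#'   on a second, disjoint branch set of the same size, so that histories
#'   contain both expansion and contraction episodes), `"lambda"`
#'   (expansions only), `"mu"` (contractions only) or `"both"` (both rates
#'   on the same branches).
#' @param shared_episodes Logical: do two simulated families share the same
#'   episode branches (the correlated regime)?
#' @param noise_p Per-internal-edge NNI perturbation probability for
#'   [add_noise()].
#' @param max_lineages Abort threshold on the total number of simulated
#'   gene lineages per family (guards memory and time under stacked
#'   episodes; such draws error and are typically redrawn by the caller).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_species = 30, lambda = 0.3, mu = 0.2,
                       episode_fraction = 0.2, rho = 10,
                       episode_mode = c("paired", "lambda", "mu", "both"),
                       shared_episodes = FALSE, noise_p = 0.1,
                       max_lineages = 5e4) {
  episode_mode <- match.arg(episode_mode)
  stopifnot(lambda >= 0, mu >= 0, rho >= 1,
            episode_fraction >= 0, episode_fraction <= 1,
            noise_p >= 0, noise_p <= 1)
  structure(list(n_species = n_species, lambda = lambda, mu = mu,
                 episode_fraction = episode_fraction, rho = rho,
                 episode_mode = episode_mode,
                 shared_episodes = shared_episodes, noise_p = noise_p,
                 max_lineages = max_lineages),
            class = "sim_params")
}

#' Simulate a species tree under a Yule process
#'
#' @param n Number of species (leaves), labelled `s1..sn`.
#' @param seed Optional integer seed.
#' @param birth Speciation rate (default 1.0).
#' @return A rooted binary ultrametric tree with labelled internal nodes.
#' @export
sim_species_tree <- function(n, seed = NULL, birth = 1.0) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n, birth = birth, death = 0)
  phy$tip.label <- paste0("s", seq_len(n))
  phy$node.label <- NULL
  label_internal_nodes(as_gtree(phy, supports = "label"))
}

## Draw the episode branch set(s) implied by the parameters. Episodes model
## ancestral expansions/contractions, so they are placed on internal
## branches; the episode fraction is taken of all non-root branches.
draw_episodes <- function(st, params) {
  nonroot <- setdiff(seq_len(gt_nnode(st)), st$root)
  eligible <- intersect(nonroot, gt_internal(st))
  if (length(eligible) < 2L) eligible <- nonroot
  n_ep <- round(params$episode_fraction * length(nonroot))
  if (n_ep == 0) return(list(lam = integer(0), mu = integer(0)))
  switch(params$episode_mode,
    lambda = list(lam = sample(eligible, min(n_ep, length(eligible))),
                  mu = integer(0)),
    mu = list(lam = integer(0),
              mu = sample(eligible, min(n_ep, length(eligible)))),
    both = {
      s <- sample(eligible, min(n_ep, length(eligible)))
      list(lam = s, mu = s)
    },
    paired = {
      s <- sample(eligible, min(n_ep, length(eligible)))
      half <- length(s) %/% 2L
      list(lam = s[seq_len(half)], mu = s[-seq_len(half)])
    })
}

#' Simulate one gene family inside a species tree
#'
#' A linear birth-death process along every species branch: each surviving
#' gene lineage independently duplicates at rate `lambda * m_b` and is lost
#' at rate `mu * m_b` on branch b (multiplier `m_b` is `rho` on episode
#' branches, 1 elsewhere; which rate is elevated follows `episode_mode`).
#' At every speciation each lineage enters both daughter branches. The
#' process starts with a single copy at the species root. Simulation is
#' exact (exponential waiting times).
#'
#' The result records, per species branch, both the true event counts and
#' the observable ones: a duplication is observable when both daughter
#' lineages leave extant descendants whose species LCAs are ancestrally
#' comparable, and is then attributed to the species LCA of all its extant
#' descendants (the oldest species node in which it is reconstructible);
#' observable losses are those implied by the surviving gene tree's path
#' through the species tree.
#'
#' @param species_tree A rooted binary species tree with branch lengths.
#' @param params [sim_params()].
#' @param episode_branches Optional integer vector of species node ids whose
#'   incoming branch carries an episode; drawn at random when `NULL`.
#' @return An object of class `sim_truth`: `gene_tree` (survivors only,
#'   leaves named `species.copyK`; `NULL` when the family went extinct),
#'   `events` (per-branch data frame with `true_dup`, `true_loss`,
#'   `obs_dup`, `obs_loss`), `copy_number` (named integer vector), and
#'   `episode_branches` (species node labels).
#' @export
sim_family <- function(species_tree, params = sim_params(),
                       episode_branches = NULL) {
  st <- label_internal_nodes(species_tree)
  nonroot <- setdiff(seq_len(gt_nnode(st)), st$root)
  if (anyNA(st$length[nonroot]))
    stop("species tree must have branch lengths")
  if (is.null(episode_branches))
    episode_branches <- draw_episodes(st, params)
  if (!is.list(episode_branches))
    episode_branches <- switch(params$episode_mode,
      lambda = list(lam = episode_branches, mu = integer(0)),
      mu = list(lam = integer(0), mu = episode_branches),
      list(lam = episode_branches, mu = episode_branches))
  mlam <- mmu <- rep(1, gt_nnode(st))
  mlam[episode_branches$lam] <- params$rho
  mmu[episode_branches$mu] <- params$rho
  true_dup <- true_loss <- integer(gt_nnode(st))
  n_nodes <- 0L
  node_times <- gt_depths(st) * 0  # absolute time of each species node
  for (v in gt_preorder(st)) {
    p <- st$parent[v]
    node_times[v] <- if (is.na(p)) 0 else node_times[p] + st$length[v]
  }
  ## recursive exact simulation; returns nested event nodes
  evolve <- function(b, pos) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > params$max_lineages)
      stop("simulated family exploded (> ", params$max_lineages,
           " lineages)")
    L <- st$length[b]
    lam <- params$lambda * mlam[b]
    mu_ <- params$mu * mmu[b]
    t_dup <- if (lam > 0) stats::rexp(1L, lam) else Inf
    t_die <- if (mu_ > 0) stats::rexp(1L, mu_) else Inf
    t_ev <- min(t_dup, t_die)
    if (pos + t_ev >= L) {
      t_here <- node_times[st$parent[b]] + L
      kids <- st$children[[b]]
      if (!length(kids))
        return(list(type = "tip", sp = b, time = t_here))
      return(list(type = "spec", sp = b, time = t_here,
                  kids = lapply(kids, evolve, pos = 0)))
    }
    t_here <- node_times[st$parent[b]] + pos + t_ev
    if (t_die <= t_dup) {
      true_loss[b] <<- true_loss[b] + 1L
      return(list(type = "death", sp = b, time = t_here))
    }
    true_dup[b] <<- true_dup[b] + 1L
    list(type = "dup", sp = b, time = t_here,
         kids = list(evolve(b, pos + t_ev), evolve(b, pos + t_ev)))
  }
  root_kids <- lapply(st$children[[st$root]], evolve, pos = 0)
  full <- list(type = "spec", sp = st$root, time = 0, kids = root_kids)
  ## prune to survivors, suppressing unary passages; compute extant-species
  ## LCA per kept node on the way up
  depth <- gt_depths(st)
  obs_dup <- integer(gt_nnode(st))
  copy_count <- stats::setNames(integer(length(gt_leaves(st))),
                                st$label[gt_leaves(st)])
  prune <- function(nd) {
    if (nd$type == "death") return(NULL)
    if (nd$type == "tip") {
      sp_lab <- st$label[nd$sp]
      copy_count[sp_lab] <<- copy_count[sp_lab] + 1L
      return(list(label = paste0(sp_lab, ".copy", copy_count[sp_lab]),
                  lca = nd$sp, time = nd$time, orig = "tip", kids = list()))
    }
    kept <- Filter(Negate(is.null), lapply(nd$kids, prune))
    if (length(kept) == 0L) return(NULL)
    if (length(kept) == 1L) return(kept[[1L]])
    lca <- kept[[1L]]$lca
    for (k in kept[-1L]) lca <- gt_lca2(st, depth, lca, k$lca)
    if (nd$type == "dup") {
      l1 <- kept[[1L]]$lca; l2 <- kept[[2L]]$lca
      if (lca == l1 || lca == l2)  # comparable LCAs: reconstructible
        obs_dup[lca] <<- obs_dup[lca] + 1L
    }
    list(label = NA_character_, lca = lca, time = nd$time,
         orig = nd$type, kids = kept)
  }
  pruned <- prune(full)
  if (is.null(pruned)) {
    events <- .sim_event_table(st, true_dup, true_loss,
                               integer(gt_nnode(st)), integer(gt_nnode(st)))
    return(structure(list(gene_tree = NULL, events = events,
                          copy_number = copy_count,
                          episode_branches = lapply(episode_branches,
                                                    function(i) st$label[i]),
                          params = params, extinct = TRUE),
                     class = "sim_truth"))
  }
  ## observable losses: walk each pruned edge's species path, counting
  ## k - 1 losses under an (inferred) speciation parent and k under a
  ## duplication parent, attributed to the off-path sibling
  obs_loss <- integer(gt_nnode(st))
  walk <- function(nd) {
    if (!length(nd$kids)) return(invisible(NULL))
    kid_lcas <- vapply(nd$kids, function(k) k$lca, 0L)
    inferred_dup <- any(kid_lcas == nd$lca)
    for (k in nd$kids) {
      path <- k$lca
      x <- k$lca
      while (x != nd$lca) {
        x <- st$parent[x]
        path <- c(x, path)
      }
      kk <- length(path) - 1L
      from <- if (inferred_dup) 1L else 2L
      if (kk >= from) {
        for (i in from:kk) {
          sib <- setdiff(st$children[[path[i]]], path[i + 1L])
          target <- if (length(sib) == 1L) sib else path[i]
          obs_loss[target] <<- obs_loss[target] + 1L
        }
      }
      walk(k)
    }
  }
  walk(pruned)
  gene_tree <- .nested_to_gtree(pruned)
  events <- .sim_event_table(st, true_dup, true_loss, obs_dup, obs_loss)
  structure(list(gene_tree = gene_tree, events = events,
                 copy_number = copy_count,
                 episode_branches = lapply(episode_branches,
                                           function(i) st$label[i]),
                 params = params, extinct = FALSE),
            class = "sim_truth")
}

.sim_event_table <- function(st, true_dup, true_loss, obs_dup, obs_loss) {
  data.frame(node = st$label,
             is_internal = lengths(st$children) > 0L,
             is_root = seq_len(gt_nnode(st)) == st$root,
             true_dup = true_dup, true_loss = true_loss,
             obs_dup = obs_dup, obs_loss = obs_loss,
             row.names = NULL, stringsAsFactors = FALSE)
}

## nested pruned structure -> gtree, branch lengths from time differences
.nested_to_gtree <- function(nested) {
  parent <- integer(0); children <- list(); label <- character(0)
  length_ <- numeric(0)
  add <- function(nd, par, t_par) {
    id <- length(parent) + 1L
    parent[id] <<- if (is.null(par)) NA_integer_ else par
    children[[id]] <<- integer(0)
    label[id] <<- nd$label
    length_[id] <<- if (is.null(par)) NA_real_ else nd$time - t_par
    if (!is.null(par)) children[[par]] <<- c(children[[par]], id)
    for (k in nd$kids) add(k, id, nd$time)
    id
  }
  add(nested, NULL, NA_real_)
  gt_new(parent, children, label, length_, rep(NA_real_, length(parent)))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated gene family",
      if (x$extinct) "(extinct)\n" else
        sprintf("with %d extant copies in %d species\n",
                sum(x$copy_number), sum(x$copy_number > 0)))
  cat(sprintf("  true events: %d duplications, %d losses; observable: %d, %d\n",
              sum(x$events$true_dup), sum(x$events$true_loss),
              sum(x$events$obs_dup), sum(x$events$obs_loss)))
  invisible(x)
}

#' Simulate two families with shared or independent rate episodes
#'
#' Under `shared_episodes = TRUE` both families carry the episode multiplier
#' on the same branch set (the correlated regime mimicking joint expansions
#' and contractions); otherwise each family draws its own branch set.
#'
#' @inheritParams sim_family
#' @return A list with elements `A` and `B` (two `sim_truth` objects over
#'   the same species tree) and `episodes` (the two branch-label sets).
#' @export
sim_correlated_pair <- function(species_tree, params = sim_params()) {
  st <- label_internal_nodes(species_tree)
  epA <- draw_episodes(st, params)
  epB <- if (params$shared_episodes) epA else draw_episodes(st, params)
  A <- sim_family(st, params, episode_branches = epA)
  B <- sim_family(st, params, episode_branches = epB)
  list(A = A, B = B,
       episodes = list(A = lapply(epA, function(i) st$label[i]),
                       B = lapply(epB, function(i) st$label[i])))
}

#' Perturb a gene tree to mimic reconstruction error
#'
#' Each internal edge is independently perturbed by a random
#' nearest-neighbour interchange with probability `noise_p`. Perturbed edges
#' receive bootstrap supports drawn uniformly from 50..89 (below the usual
#' rearrangement cutoff), untouched internal edges from 90..100. The leaf
#' set is unchanged.
#'
#' @param gene_tree A rooted binary gene tree.
#' @param noise_p Per-internal-edge perturbation probability.
#' @param seed Optional integer seed.
#' @return The (possibly perturbed) tree with supports set.
#' @export
add_noise <- function(gene_tree, noise_p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(gt_is_binary(gene_tree))
  tree <- gene_tree
  internal <- setdiff(gt_internal(tree), tree$root)
  perturbed <- logical(gt_nnode(tree))
  for (v in internal) {
    if (stats::runif(1L) >= noise_p) next
    p <- tree$parent[v]
    sib <- setdiff(tree$children[[p]], v)
    if (length(sib) != 1L) next
    kids <- tree$children[[v]]
    z <- kids[sample.int(2L, 1L)]
    ## swap z (child of v) with sib (child of p)
    tree$children[[v]] <- c(setdiff(kids, z), sib)
    tree$children[[p]] <- c(setdiff(tree$children[[p]], sib), z)
    ## keep v in p's children (setdiff removed only sib)
    tree$parent[z] <- p
    tree$parent[sib] <- v
    perturbed[v] <- TRUE
  }
  for (v in setdiff(gt_internal(tree), tree$root)) {
    tree$support[v] <- if (perturbed[v]) sample(50:89, 1L) else
      sample(90:100, 1L)
  }
  tree
}

#' Branch event table from simulator ground truth
#'
#' Converts a `sim_truth` object into the same per-branch event table that
#' [branch_events()] builds from reconciliations, using either the
#' observable events (default; what parsimony can reconstruct) or the true
#' ones.
#'
#' @param sim A [sim_family()] result.
#' @param species_tree The species tree the family was simulated on.
#' @param family Family identifier stored with the table.
#' @param observable Use observable (default) or true event counts.
#' @return A `branch_events` data frame.
#' @export
truth_branch_events <- function(sim, species_tree, family = "family",
                                observable = TRUE) {
  stopifnot(inherits(sim, "sim_truth"))
  st <- label_internal_nodes(species_tree)
  ev <- sim$events
  stopifnot(identical(ev$node, st$label))
  dup <- if (observable) ev$obs_dup else ev$true_dup
  loss <- if (observable) ev$obs_loss else ev$true_loss
  out <- data.frame(node = ev$node, is_internal = ev$is_internal,
                    is_root = ev$is_root,
                    dup = as.integer(dup), loss = as.integer(loss),
                    net = as.integer(dup) - as.integer(loss),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "family") <- family
  attr(out, "species_key") <- gt_canonical(st)
  class(out) <- c("branch_events", "data.frame")
  out
}
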