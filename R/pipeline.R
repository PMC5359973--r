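#' Run the full duplication-loss coevolution pipeline
#'
#' Orchestrates the stages in the canonical order - root, rearrange,
#' reconcile, map events to species branches, test for coevolution - for two
#' or more gene families against a common species tree, writing per-family
#' event tables, a joint coevolution report and a machine-readable manifest.
#' Outputs are deterministic given identical inputs and seed.
#'
#' @param config A named list (or path of a `key=value`, one-per-line config
#'   file) with entries:
#'   \describe{
#'     \item{species}{path of the species tree (newick).}
#'     \item{families}{named character vector / list: family id -> newick
#'       file of its gene tree(s) (several per family may be given).}
#'     \item{map}{optional path of a 2-column TSV leaf map; otherwise
#'       `delimiter`/`field` extraction is used (defaults `.` and 1).}
#'     \item{cutoff, dup, cond, loss, min_events, seed}{optional numeric
#'       stage parameters.}
#'     \item{rearrange}{logical, default TRUE.}
#'   }
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the reconciliations, branch event tables
#'   and coevolution test objects; files are written to `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L)
    config <- .read_config(config)
  for (req in c("species", "families")) {
    if (is.null(config[[req]]))
      stop("pipeline config: missing required entry '", req, "'")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  params <- recon_params(dup = as.numeric(config$dup %||% 1.5),
                         cond = as.numeric(config$cond %||% 0),
                         loss = as.numeric(config$loss %||% 1))
  cutoff <- as.numeric(config$cutoff %||% 90)
  species_tree <- tryCatch(
    label_internal_nodes(parse_newick(config$species, supports = "label")),
    error = function(e) stop("stage species-tree: ", conditionMessage(e)))
  fams <- config$families
  if (length(fams) < 2L)
    stop("stage input: need gene trees for at least 2 families")
  tables <- list(); recs_all <- list(); costs <- list()
  for (fam in names(fams)) {
    files <- unlist(fams[[fam]])
    recs <- lapply(files, function(f) {
      gt <- tryCatch(parse_newick(f),
                     error = function(e) stop("stage read[", fam, "]: ",
                                              conditionMessage(e)))
      lm <- tryCatch(
        build_leaf_map(gt, species_tree,
                       delimiter = config$delimiter %||% ".",
                       field = as.integer(config$field %||% 1L),
                       table = config$map),
        error = function(e) stop("stage leaf-map[", fam, "]: ",
                                 conditionMessage(e)))
      if (!identical(config$rearrange %||% TRUE, FALSE) &&
          !isFALSE(as.logical(config$rearrange %||% TRUE)))
        gt <- rearrange_tree(gt, species_tree, lm, params,
                             cutoff = cutoff, seed = seed)
      reconcile(gt, species_tree, lm, params)
    })
    recs_all[[fam]] <- recs
    costs[[fam]] <- vapply(recs, function(r) r$cost, 0)
    tables[[fam]] <- branch_events(recs, species_tree, family = fam)
    utils::write.table(tables[[fam]],
                       file.path(outdir, paste0("events_", fam, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    loss_tab <- do.call(rbind, lapply(recs, function(r)
      data.frame(species_node = names(r$losses),
                 losses = as.integer(r$losses))))
    loss_tab <- stats::aggregate(losses ~ species_node, loss_tab, sum)
    utils::write.table(loss_tab,
                       file.path(outdir, paste0("losses_", fam, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  famA <- names(fams)[1L]
  tests <- list()
  for (famB in names(fams)[-1L]) {
    key <- paste0(famA, "_vs_", famB)
    tests[[key]] <- coevolution_test(
      tables[[famA]], tables[[famB]],
      min_events = as.numeric(config$min_events %||% 0))
    out <- utils::capture.output(print(tests[[key]]))
    writeLines(out, file.path(outdir, paste0("coevolution_", key, ".txt")))
  }
  manifest <- list(
    package = "dupcoev",
    version = as.character(utils::packageVersion("dupcoev")),
    seed = seed, cutoff = cutoff,
    weights = unclass(params),
    families = lapply(fams, function(x) as.character(unlist(x))),
    species = config$species,
    costs = costs,
    headline_p = lapply(tests, function(t)
      if (is.null(t$headline)) NA else t$headline$p.value))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reconciliations = recs_all, tables = tables,
                 tests = tests, manifest = manifest))
}

.read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1L])
    val <- trimws(paste(p[-1L], collapse = "="))
    if (key == "family") {
      ## family=<id>:<file>[,<file>...]
      parts <- strsplit(val, ":", fixed = TRUE)[[1L]]
      out$families[[parts[1L]]] <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
    } else {
      out[[key]] <- val
    }
  }
  out
}
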