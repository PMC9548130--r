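#' Construct a connectome object
#'
#' A connectome couples an ordered neuron registry to two weight matrices:
#' a symmetric gap-junction (electrical synapse) matrix and a directed
#' chemical-synapse matrix, both in units of contact counts. Matrix order is
#' the neuron-table order and is preserved through ablation and persistence,
#' so trace columns are reproducible across runs.
#'
#' @param neurons data.frame with columns `name`, `class`, `category`
#'   (one of `"sensory"`, `"inter"`, `"motor"`), `inhibitory` (logical).
#' @param gap N x N nonnegative symmetric matrix of gap-junction contacts.
#' @param chem N x N nonnegative matrix of chemical contacts, pre in rows,
#'   post in columns.
#' @param version_tag free-text label identifying the wiring edition.
#' @param ablated character vector of neuron names whose connections have
#'   been structurally removed (kept in the registry; see [ablate()]).
#' @return An object of class `connectome`.
#' @export
connectome <- function(neurons, gap, chem, version_tag = "unversioned",
                       ablated = character()) {
  neurons <- validate_neuron_table(neurons)
  n <- nrow(neurons)
  gap <- as.matrix(gap)
  chem <- as.matrix(chem)
  if (!identical(dim(gap), c(n, n)) || !identical(dim(chem), c(n, n)))
    stop("gap and chem must be ", n, " x ", n, " matrices matching the neuron table")
  dimnames(gap) <- dimnames(chem) <- list(neurons$name, neurons$name)
  if (any(gap < 0) || any(chem < 0))
    stop("synaptic weights must be nonnegative")
  if (any(diag(gap) != 0) || any(diag(chem) != 0))
    stop("self-connections (nonzero diagonal) are not allowed")
  if (!isTRUE(all.equal(gap, t(gap), tolerance = 0)))
    stop("gap-junction matrix must be symmetric; symmetrize at load time")
  structure(
    list(neurons = neurons, gap = gap, chem = chem,
         version_tag = as.character(version_tag),
         ablated = sort(unique(as.character(ablated)))),
    class = "connectome")
}

validate_neuron_table <- function(neurons) {
  neurons <- as.data.frame(neurons, stringsAsFactors = FALSE)
  required <- c("name", "class", "category", "inhibitory")
  missing <- setdiff(required, names(neurons))
  if (length(missing))
    stop("neuron table lacks column(s): ", paste(missing, collapse = ", "))
  neurons$name <- as.character(neurons$name)
  neurons$class <- as.character(neurons$class)
  neurons$category <- as.character(neurons$category)
  neurons$inhibitory <- as.logical(neurons$inhibitory)
  if (anyDuplicated(neurons$name))
    stop("duplicate neuron name(s): ",
         paste(unique(neurons$name[duplicated(neurons$name)]), collapse = ", "))
  bad <- !neurons$category %in% c("sensory", "inter", "motor")
  if (any(bad))
    stop("unknown category for ", paste(neurons$name[bad], collapse = ", "),
         " (expected sensory, inter or motor)")
  if (anyNA(neurons$inhibitory))
    stop("inhibitory flag must be TRUE/FALSE for every neuron")
  rownames(neurons) <- NULL
  neurons[required]
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$neurons), " neurons (",
      sum(x$neurons$category == "sensory"), " sensory, ",
      sum(x$neurons$category == "inter"), " inter, ",
      sum(x$neurons$category == "motor"), " motor), ",
      sum(x$gap > 0) / 2, " gap pairs, ", sum(x$chem > 0),
      " chemical edges, version ", x$version_tag, "\n", sep = "")
  if (length(x$ablated))
    cat("  ablated:", paste(x$ablated, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.connectome <- function(x) c(nrow(x$neurons), nrow(x$neurons))

#' Number of neurons in a connectome
#' @param connectome a `connectome` object.
#' @return integer count.
#' @export
n_neurons <- function(connectome) nrow(connectome$neurons)

#' Load a connectome from neuron-table and edge-list files
#'
#' Reads the two-file CSV dialect: a neuron table with header
#' `name,class,category,inhibitory` and an edge list with header
#' `pre,post,type,weight` where `type` is `gap` or `chemical`. Duplicate
#' (pre, post, type) rows are summed. Gap edges are summed per unordered
#' pair and mirrored into a symmetric matrix, because electrical synapses
#' are bidirectional while published wiring tables list them once per
#' reconstruction direction; a warning reports pairs given on one side only.
#'
#' @param neuron_table_path path to the neuron CSV.
#' @param edge_list_path path to the edge CSV.
#' @param version_tag label recorded on the returned object; defaults to the
#'   edge-list file name.
#' @return A validated [connectome()].
#' @seealso [read_connectome_json()] for the single-file JSON dialect,
#'   [write_connectome()] for the writers.
#' @export
load_connectome <- function(neuron_table_path, edge_list_path,
                            version_tag = basename(edge_list_path)) {
  for (p in c(neuron_table_path, edge_list_path))
    if (!file.exists(p)) stop("no such file: ", p)
  neurons <- utils::read.csv(neuron_table_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edge_list_path, stringsAsFactors = FALSE)
  build_connectome_from_edges(neurons, edges, version_tag)
}

build_connectome_from_edges <- function(neurons, edges, version_tag) {
  neurons <- validate_neuron_table(neurons)
  n <- nrow(neurons)
  gap <- chem <- matrix(0, n, n, dimnames = list(neurons$name, neurons$name))
  if (nrow(edges)) {
    required <- c("pre", "post", "type", "weight")
    missing <- setdiff(required, names(edges))
    if (length(missing))
      stop("edge list lacks column(s): ", paste(missing, collapse = ", "))
    for (col in c("pre", "post")) {
      unknown <- !edges[[col]] %in% neurons$name
      if (any(unknown))
        stop("edge row(s) ", paste(which(unknown), collapse = ", "),
             " reference undeclared neuron(s): ",
             paste(unique(edges[[col]][unknown]), collapse = ", "))
    }
    bad_type <- !edges$type %in% c("gap", "chemical")
    if (any(bad_type))
      stop("edge row(s) ", paste(which(bad_type), collapse = ", "),
           " have type outside {gap, chemical}")
    if (any(edges$weight < 0))
      stop("edge row(s) ", paste(which(edges$weight < 0), collapse = ", "),
           " have negative weight")
    if (any(edges$pre == edges$post))
      stop("self-edge(s) at row(s) ",
           paste(which(edges$pre == edges$post), collapse = ", "))
    is_gap <- edges$type == "gap"
    for (k in which(!is_gap))
      chem[edges$pre[k], edges$post[k]] <-
        chem[edges$pre[k], edges$post[k]] + edges$weight[k]
    # gap: accumulate directed entries first, then fold per unordered pair
    graw <- matrix(0, n, n, dimnames = dimnames(gap))
    for (k in which(is_gap))
      graw[edges$pre[k], edges$post[k]] <-
        graw[edges$pre[k], edges$post[k]] + edges$weight[k]
    # reciprocal listings record the same contacts seen from the two
    # reconstruction directions: keep the larger per-direction total and
    # mirror it, so (A,B,w) alone and (A,B,w)+(B,A,w) both give weight w
    one_sided <- ((graw > 0) != (t(graw) > 0)) & upper.tri(graw)
    if (any(one_sided)) {
      pairs <- which(one_sided, arr.ind = TRUE)
      warning("gap edge(s) listed in one direction only, mirrored: ",
              paste(neurons$name[pairs[, 1]], neurons$name[pairs[, 2]],
                    sep = "~", collapse = ", "))
    }
    gap <- pmax(graw, t(graw))
  }
  connectome(neurons, gap, chem, version_tag)
}

#' Read a connectome from the single-file JSON dialect
#'
#' Expects top-level keys `neurons` (records with name/class/category/
#' inhibitory), `gap_edges` and `chem_edges` (records with pre/post/weight),
#' and optionally `version_tag`.
#'
#' @param path JSON file path.
#' @return A validated [connectome()].
#' @export
read_connectome_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- rbind(
    if (!is.null(obj$gap_edges) && NROW(obj$gap_edges))
      cbind(as.data.frame(obj$gap_edges), type = "gap"),
    if (!is.null(obj$chem_edges) && NROW(obj$chem_edges))
      cbind(as.data.frame(obj$chem_edges), type = "chemical"))
  if (is.null(edges)) edges <- data.frame(pre = character(), post = character(),
                                          type = character(), weight = numeric())
  build_connectome_from_edges(as.data.frame(obj$neurons), edges,
                              version_tag = obj$version_tag %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a connectome to disk
#'
#' Emits either the two-file CSV dialect (`<stem>_neurons.csv`,
#' `<stem>_edges.csv`) or the single-file JSON dialect, matching what
#' [load_connectome()] / [read_connectome_json()] read. Gap pairs are
#' written in both directions with their full weight, the reciprocal form
#' the loader folds back, so a load round-trip reproduces the matrices
#' exactly and without warnings.
#'
#' @param connectome a `connectome`.
#' @param stem output path stem (CSV) or file path (JSON).
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the file path(s) written.
#' @export
write_connectome <- function(connectome, stem, format = c("csv", "json")) {
  format <- match.arg(format)
  nm <- connectome$neurons$name
  gidx <- which(connectome$gap > 0, arr.ind = TRUE)
  cidx <- which(connectome$chem > 0, arr.ind = TRUE)
  gap_edges <- data.frame(pre = nm[gidx[, 1]], post = nm[gidx[, 2]],
                          weight = connectome$gap[gidx])
  chem_edges <- data.frame(pre = nm[cidx[, 1]], post = nm[cidx[, 2]],
                           weight = connectome$chem[cidx])
  if (format == "csv") {
    paths <- paste0(stem, c("_neurons.csv", "_edges.csv"))
    utils::write.csv(connectome$neurons, paths[1], row.names = FALSE,
                     quote = FALSE)
    edges <- rbind(
      if (nrow(gap_edges)) cbind(gap_edges, type = "gap"),
      if (nrow(chem_edges)) cbind(chem_edges, type = "chemical"))
    if (is.null(edges))
      edges <- data.frame(pre = character(), post = character(),
                          weight = numeric(), type = character())
    utils::write.csv(edges[c("pre", "post", "type", "weight")], paths[2],
                     row.names = FALSE, quote = FALSE)
    invisible(paths)
  } else {
    jsonlite::write_json(
      list(version_tag = connectome$version_tag,
           neurons = connectome$neurons,
           gap_edges = gap_edges, chem_edges = chem_edges),
      stem, auto_unbox = TRUE, digits = NA)
    invisible(stem)
  }
}

# Aliases for circuit-level neuron groupings that are not anatomical class
# names: the command-interneuron set driving backward locomotion and the
# backward-locomotion motor classes.
group_aliases <- function() {
  list(
    CI = c("AVA", "AVD", "AVE"),
    backward_motor = c("VA", "DA", "VD", "DD", "AS"))
}

#' Resolve a neuron group by class label, alias, or explicit name
#'
#' A bilateral class label (e.g. `"AWB"`) resolves to its left/right members,
#' a motor class (e.g. `"VA"`) to all numbered members, the alias `"CI"` to
#' the AVA/AVD/AVE command-interneuron classes, `"backward_motor"` to the
#' VA, DA, VD, DD and AS classes, and an explicit neuron name to itself.
#' Members are returned in matrix (neuron-table) order.
#'
#' @param connectome a `connectome`.
#' @param group_name class label, alias, or neuron name.
#' @return A list with `group_name` and `members` (character vector).
#' @export
resolve_group <- function(connectome, group_name) {
  nm <- connectome$neurons$name
  cls <- connectome$neurons$class
  aliases <- group_aliases()
  members <-
    if (group_name %in% names(aliases)) nm[cls %in% aliases[[group_name]]]
    else if (group_name %in% cls) nm[cls == group_name]
    else if (group_name %in% nm) group_name
    else stop("unknown group '", group_name, "'; available classes: ",
              paste(sort(unique(cls)), collapse = ", "),
              "; aliases: ", paste(names(aliases), collapse = ", "))
  if (!length(members))
    stop("group '", group_name, "' resolves to no neurons in this connectome")
  list(group_name = group_name, members = members)
}

#' Structurally ablate neurons
#'
#' Returns a new connectome in which every gap and chemical weight into or
#' out of each ablated neuron is zero. The neuron stays in the registry (and
#' in the state vector during simulation, isolated at its leak equilibrium),
#' so matrix indices and trace columns are stable across ablation screens.
#' Ablating a neuron twice is a no-op, not an error.
#'
#' @param connectome a `connectome`.
#' @param ablations character vector of neuron names, or a group as returned
#'   by [resolve_group()].
#' @return A new `connectome` with the `ablated` field extended.
#' @export
ablate <- function(connectome, ablations) {
  if (is.list(ablations)) ablations <- ablations$members
  ablations <- unique(as.character(ablations))
  if (!length(ablations)) return(connectome)
  unknown <- setdiff(ablations, connectome$neurons$name)
  if (length(unknown))
    stop("cannot ablate unknown neuron(s): ", paste(unknown, collapse = ", "))
  idx <- match(ablations, connectome$neurons$name)
  gap <- connectome$gap; chem <- connectome$chem
  gap[idx, ] <- 0; gap[, idx] <- 0
  chem[idx, ] <- 0; chem[, idx] <- 0
  connectome(connectome$neurons, gap, chem, connectome$version_tag,
             ablated = union(connectome$ablated, ablations))
}
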