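#' Build the standard 6-source reading network
#'
#' Constructs the bilateral three-level hierarchy used throughout the
#' package: occipital cortex (OCC, level 1), ventral occipitotemporal
#' cortex (vOT, level 2) and inferior frontal gyrus (IFG, level 3) in each
#' hemisphere, with MNI prior locations mirrored across the midline.
#'
#' @return An object of class `network_spec`: a data frame with one row per
#'   node and columns `id`, `label`, `hemisphere`, `level`, `x`, `y`, `z`
#'   (MNI mm).
#' @export
#' @examples
#' net <- build_standard_network()
#' nrow(net)  # 6
build_standard_network <- function() {
  build_network(
    labels      = c("OCC", "vOT", "IFG"),
    levels      = c(OCC = 1L, vOT = 2L, IFG = 3L),
    locations   = rbind(OCC = c(15, -95, 2),
                        vOT = c(44, -58, -15),
                        IFG = c(48, 28, 0)),
    hemispheres = c("left", "right")
  )
}

#' Build a (possibly reduced) source network
#'
#' General constructor for source hierarchies.  `locations` give the
#' right-hemisphere coordinates; left-hemisphere homologues are mirrored
#' across x.  Single-hemisphere networks are permitted (used for small test
#' configurations) but connection grouping then degenerates to singletons.
#'
#' @param labels character vector of region labels.
#' @param levels named integer vector: hierarchy rank per label.
#' @param locations matrix with one row per label: MNI mm, x > 0
#'   (right-hemisphere convention; the left homologue is `-x`).
#' @param hemispheres subset of `c("left", "right")`.
#' @return A `network_spec` data frame.
#' @export
build_network <- function(labels, levels, locations,
                          hemispheres = c("left", "right")) {
  stopifnot(length(labels) >= 1, all(labels %in% names(levels)),
            all(labels %in% rownames(locations)),
            all(hemispheres %in% c("left", "right")))
  rows <- list()
  for (h in hemispheres) {
    sgn <- if (h == "left") -1 else 1
    for (lab in labels) {
      loc <- locations[lab, ]
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(toupper(substr(h, 1, 1)), "_", lab),
        label = lab, hemisphere = h, level = as.integer(levels[[lab]]),
        x = sgn * abs(loc[1]), y = loc[2], z = loc[3],
        stringsAsFactors = FALSE)
    }
  }
  net <- do.call(rbind, rows)
  rownames(net) <- net$id
  class(net) <- c("network_spec", "data.frame")
  net
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d sources, %d level(s), hemispheres: %s\n",
              nrow(x), length(unique(x$level)),
              paste(unique(x$hemisphere), collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Classify a directed connection by its endpoints
#'
#' Connection class is a pure function of the two endpoint nodes:
#' same hemisphere with target above source is `forward`, below is
#' `backward`; different hemisphere at the same level is `lateral`;
#' different hemisphere across levels is `diagonal`; identical endpoints
#' are `self`.  Level-skipping within a hemisphere (e.g. OCC to IFG) is
#' still forward/backward, not diagonal.
#'
#' @param network a `network_spec`.
#' @param source,target node ids.
#' @return one of `"forward"`, `"backward"`, `"lateral"`, `"diagonal"`,
#'   `"self"`.
#' @export
classify_connection <- function(network, source, target) {
  s <- network[source, ]; t <- network[target, ]
  if (is.na(s$id) || is.na(t$id)) stop("unknown node id")
  if (source == target) return("self")
  if (s$hemisphere == t$hemisphere) {
    if (t$level > s$level) "forward" else "backward"
  } else {
    if (t$level == s$level) "lateral" else "diagonal"
  }
}

connection_id <- function(source, target) paste0(source, "->", target)

#' Enumerate all directed connections of a network
#'
#' All ordered pairs of distinct nodes, each classified; a network with n
#' nodes yields n(n-1) connections.
#'
#' @param network a `network_spec`.
#' @return data frame with columns `id`, `source`, `target`, `klass`.
#' @export
enumerate_connections <- function(network) {
  stopifnot(nrow(network) >= 2)
  ids <- network$id
  grid <- expand.grid(source = ids, target = ids,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid$klass <- vapply(seq_len(nrow(grid)), function(i)
    classify_connection(network, grid$source[i], grid$target[i]), "")
  grid$id <- connection_id(grid$source, grid$target)
  out <- grid[order(grid$source, grid$target), c("id", "source", "target", "klass")]
  rownames(out) <- NULL
  out
}

mirror_node <- function(network, id) {
  n <- network[id, ]
  other <- network$id[network$label == n$label &
                        network$hemisphere != n$hemisphere]
  if (length(other) == 1) other else NA_character_
}

#' Group connections that are switched together
#'
#' Applies the model-space constraint rules: diagonal (cross-hemisphere,
#' cross-level) connections are excluded; every within-hemisphere forward or
#' backward connection is bundled with its opposite-hemisphere mirror; every
#' homotopic lateral connection is bundled with its reciprocal.  For the
#' standard 6-source network this yields nine groups (six mirrored
#' forward/backward pairs and three bidirectional lateral bundles).
#'
#' Nodes without an opposite-hemisphere homologue produce singleton groups,
#' flagged in the result.  Self-connections are excluded by default; they
#' can be pooled into a single switchable group or kept one-per-node, which
#' is used by small test networks where self-modulation is treated as an
#' explicit model dimension.
#'
#' @param network a `network_spec`.
#' @param include_self `"none"` (default), `"pooled"` (all self-connections
#'   as one group) or `"each"`.
#' @return An object of class `connection_groups`: a list of groups, each a
#'   list with `id`, `kind`, `members` (data frame `source`, `target`) and
#'   `flagged` (TRUE when a mirror was missing).
#' @export
independent_groups <- function(network,
                               include_self = c("none", "pooled", "each")) {
  include_self <- match.arg(include_self)
  conns <- enumerate_connections(network)
  groups <- list()
  seen <- character(0)
  add_group <- function(members, kind, flagged = FALSE) {
    key <- paste(sort(connection_id(members$source, members$target)),
                 collapse = "|")
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    id <- paste(connection_id(members$source, members$target), collapse = " & ")
    groups[[length(groups) + 1L]] <<-
      list(id = id, kind = kind, members = members, flagged = flagged)
    invisible(NULL)
  }
  # forward/backward: pair with the opposite-hemisphere mirror
  fb <- conns[conns$klass %in% c("forward", "backward"), ]
  fb <- fb[order(abs(network[fb$target, "level"] - network[fb$source, "level"]),
                 pmin(network[fb$source, "level"], network[fb$target, "level"]),
                 match(fb$klass, c("forward", "backward")), fb$source), ]
  for (i in seq_len(nrow(fb))) {
    s <- fb$source[i]; t <- fb$target[i]
    ms <- mirror_node(network, s); mt <- mirror_node(network, t)
    if (!is.na(ms) && !is.na(mt)) {
      add_group(data.frame(source = c(s, ms), target = c(t, mt),
                           stringsAsFactors = FALSE), "mirrored-pair")
    } else {
      add_group(data.frame(source = s, target = t, stringsAsFactors = FALSE),
                "singleton", flagged = TRUE)
    }
  }
  # lateral: homotopic pairs, bundled bidirectionally
  lat <- conns[conns$klass == "lateral", ]
  lat <- lat[order(network[lat$source, "level"], lat$source), ]
  for (i in seq_len(nrow(lat))) {
    s <- lat$source[i]; t <- lat$target[i]
    if (network[s, "label"] != network[t, "label"]) next  # heterotopic: excluded
    add_group(data.frame(source = c(s, t), target = c(t, s),
                         stringsAsFactors = FALSE), "reciprocal-lateral")
  }
  if (include_self == "pooled") {
    add_group(data.frame(source = network$id, target = network$id,
                         stringsAsFactors = FALSE), "self")
  } else if (include_self == "each") {
    for (id in network$id)
      add_group(data.frame(source = id, target = id,
                           stringsAsFactors = FALSE), "self")
  }
  structure(groups, class = "connection_groups", network = network)
}

#' @export
print.connection_groups <- function(x, ...) {
  cat(sprintf("<connection_groups> %d group(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  [%d] %-18s %s%s\n", i, x[[i]]$kind, x[[i]]$id,
                if (isTRUE(x[[i]]$flagged)) "  (no homologue)" else ""))
  invisible(x)
}

#' Enumerate the binary model space over connection groups
#'
#' Every on/off assignment of condition modulation over the groups, in
#' little-endian binary counting order (pattern index 0 is the null model,
#' bit j of the index switches group j).  Nine groups give the full
#' 512-model space.
#'
#' @param groups a `connection_groups` object.
#' @param max_groups refuse enumeration beyond this many groups
#'   (default 16, i.e. 65536 models).
#' @return An object of class `model_space`: list with `groups` and
#'   `patterns` (a 2^k x k 0/1 matrix, one row per model).
#' @export
enumerate_model_space <- function(groups, max_groups = 16) {
  k <- length(groups)
  if (k > max_groups)
    stop(sprintf("%d groups would enumerate %.0f models (cap %d groups)",
                 k, 2^k, max_groups))
  n <- as.integer(2^k)
  patterns <- matrix(0L, n, max(k, 1L))
  if (k > 0) {
    idx <- 0:(n - 1)
    for (j in seq_len(k)) patterns[, j] <- bitwAnd(idx %/% 2L^(j - 1L), 1L)
    colnames(patterns) <- vapply(groups, `[[`, "", "id")
  } else {
    patterns <- matrix(integer(0), 1, 0)
  }
  structure(list(groups = groups, patterns = patterns),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("<model_space> %d model(s) over %d group(s)\n",
              nrow(x$patterns), length(x$groups)))
  invisible(x)
}

#' Extract one modulation pattern from a model space
#'
#' @param space a `model_space`.
#' @param index model index, 1-based row of the pattern matrix (model 1 is
#'   the null model).
#' @return A `modulation_pattern`: list with `groups`, `bits` and `index`.
#' @export
model_pattern <- function(space, index) {
  stopifnot(index >= 1, index <= nrow(space$patterns))
  structure(list(groups = space$groups,
                 bits = as.integer(space$patterns[index, ]),
                 index = as.integer(index)),
            class = "modulation_pattern")
}

#' Map connections to their group index under a pattern
#'
#' @param pattern a `modulation_pattern`.
#' @param connections data frame with `source`, `target`.
#' @return integer vector: group index per connection, NA when ungrouped.
#' @keywords internal
pattern_group_of <- function(pattern, connections) {
  ids <- connection_id(connections$source, connections$target)
  out <- rep(NA_integer_, length(ids))
  for (g in seq_along(pattern$groups)) {
    m <- pattern$groups[[g]]$members
    out[ids %in% connection_id(m$source, m$target)] <- g
  }
  out
}

#' Serialize a network and its model space to JSON
#'
#' @param network a `network_spec`.
#' @param space optional `model_space` built on that network.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
modelspace_to_json <- function(network, space = NULL, path) {
  obj <- list(nodes = network[, c("id", "label", "hemisphere", "level",
                                  "x", "y", "z")])
  if (!is.null(space)) {
    obj$groups <- lapply(space$groups, function(g)
      list(id = g$id, kind = g$kind,
           members = connection_id(g$members$source, g$members$target)))
    obj$n_models <- nrow(space$patterns)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
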