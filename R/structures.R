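#' Grouping-tree grammar rules
#'
#' A grouping tree organises the moving elements of a scene into nested
#' reference frames: leaves are elements, internal nodes are groups, and the
#' (implicit) root is the stationary world. The grammar below controls which
#' trees are admissible. The defaults are frozen to the rule-set under which
#' exhaustive enumeration reproduces the known structure counts for small
#' scenes (2 structures for one element, 12 for two, 264 for three).
#'
#' Under the default rules a group node must have at least two children
#' (groups exist to relate several things), with one exception: an element may
#' be promoted to a singleton group directly under the world -- giving it its
#' own reference frame -- but only in scenes that already contain at least one
#' multi-element group. Chain groups (a group whose only child is another
#' group) are never admitted.
#'
#' @param allow_singleton_top allow singleton element-wrapping groups as
#'   children of the world.
#' @param singleton_needs_multigroup require at least one multi-element group
#'   in the tree before any singleton group is admitted.
#' @param allow_singleton_nested allow singleton groups inside other groups.
#' @return a named list of class `"hm_grammar"`.
#' @export
grammar_rules <- function(allow_singleton_top = TRUE,
                          singleton_needs_multigroup = TRUE,
                          allow_singleton_nested = FALSE) {
  structure(list(allow_singleton_top = isTRUE(allow_singleton_top),
                 singleton_needs_multigroup = isTRUE(singleton_needs_multigroup),
                 allow_singleton_nested = isTRUE(allow_singleton_nested)),
            class = "hm_grammar")
}

## all set partitions of an integer vector, canonical order: the block holding
## the smallest element comes first, generated recursively
set_partitions <- function(v) {
  if (length(v) == 0L) return(list(list()))
  if (length(v) == 1L) return(list(list(v)))
  first <- v[1]; rest <- v[-1]
  out <- list()
  for (p in set_partitions(rest)) {
    # put `first` into each existing block, or into its own block
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- sort(c(first, q[[k]]))
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  lapply(out, function(p) p[order(vapply(p, min, numeric(1)))])
}

## nested "unit" representation used during enumeration:
## list(type = "element", id = i) or list(type = "group", children = list of units)
.unit_element <- function(i) list(type = "element", id = i)
.unit_group <- function(children) list(type = "group", children = children)

## all ways to organise element set S (|S| >= 2) as a single rooted group
.group_structures <- function(S, rules) {
  stopifnot(length(S) >= 2L)
  out <- list()
  for (p in set_partitions(S)) {
    if (length(p) < 2L) next   # a chain group (single child) is not admitted
    child_opts <- lapply(p, function(b) {
      if (length(b) == 1L) {
        opts <- list(.unit_element(b))
        if (rules$allow_singleton_nested)
          opts <- c(opts, list(.unit_group(list(.unit_element(b)))))
        opts
      } else {
        lapply(.group_structures(b, rules), identity)
      }
    })
    for (combo in .cartesian(child_opts))
      out[[length(out) + 1L]] <- .unit_group(combo)
  }
  out
}

## cartesian product of a list of option-lists, deterministic order
.cartesian <- function(opts) {
  res <- list(list())
  for (o in opts) {
    res <- unlist(lapply(res, function(acc) {
      lapply(o, function(x) c(acc, list(x)))
    }), recursive = FALSE)
  }
  res
}

## flatten a forest of units into node arrays; elements get ids 1..n, groups
## are appended in pre-order over top-level units sorted by smallest member
.unit_members <- function(u) {
  if (u$type == "element") return(u$id)
  sort(unlist(lapply(u$children, .unit_members)))
}

.flatten_forest <- function(units, n) {
  parent <- integer(n); kind <- rep("element", n)
  members <- as.list(seq_len(n))
  add_unit <- function(u, parent_id) {
    if (u$type == "element") {
      parent[u$id] <<- parent_id
      return(invisible(NULL))
    }
    gid <- length(parent) + 1L
    parent[gid] <<- parent_id
    kind[gid] <<- "group"
    members[[gid]] <<- .unit_members(u)
    kids <- u$children[order(vapply(u$children, function(x) min(.unit_members(x)),
                                    numeric(1)))]
    for (k in kids) add_unit(k, gid)
  }
  units <- units[order(vapply(units, function(x) min(.unit_members(x)), numeric(1)))]
  for (u in units) add_unit(u, 0L)
  new_grouping_tree(n, parent, kind, members)
}

new_grouping_tree <- function(n, parent, kind, members) {
  anc <- vector("list", n)
  for (e in seq_len(n)) {
    path <- integer(0); node <- e
    while (node != 0L) { path <- c(path, node); node <- parent[node] }
    anc[[e]] <- path
  }
  structure(list(n_elements = n, parent = parent, kind = kind,
                 members = members, ancestors = anc,
                 n_groups = sum(kind == "group")),
            class = "grouping_tree")
}

#' Enumerate grouping trees
#'
#' Enumerates every admissible grouping tree over `n_elements` moving
#' elements under the grammar in [grammar_rules()]. Nodes are indexed with
#' elements first (`1..n`), then group nodes in a canonical pre-order;
#' `parent = 0` denotes the world. Enumeration order is deterministic.
#'
#' @param n_elements number of moving elements (1 to 4).
#' @param rules grammar rule-set, see [grammar_rules()].
#' @return list of `grouping_tree` objects.
#' @examples
#' length(enumerate_grouping_trees(2))  # 2
#' @export
enumerate_grouping_trees <- function(n_elements, rules = grammar_rules()) {
  if (!is.numeric(n_elements) || length(n_elements) != 1L ||
      n_elements < 1 || n_elements != round(n_elements))
    stop("`n_elements` must be a single integer >= 1")
  if (n_elements > 4)
    stop("enumeration is supported for up to 4 elements")
  n <- as.integer(n_elements)
  forests <- list()
  for (p in set_partitions(seq_len(n))) {
    multi <- p[lengths(p) >= 2L]
    singles <- p[lengths(p) == 1L]
    multi_opts <- lapply(multi, function(b) .group_structures(b, rules))
    wrap_ok <- rules$allow_singleton_top &&
      (!rules$singleton_needs_multigroup || length(multi) > 0L)
    single_opts <- lapply(singles, function(b) {
      opts <- list(.unit_element(b))
      if (wrap_ok) opts <- c(opts, list(.unit_group(list(.unit_element(b)))))
      opts
    })
    for (combo in .cartesian(c(multi_opts, single_opts)))
      forests[[length(forests) + 1L]] <- combo
  }
  trees <- lapply(forests, .flatten_forest, n = n)
  sigs <- vapply(trees, .tree_signature, character(1))
  trees <- trees[!duplicated(sigs)]
  trees[order(vapply(trees, .tree_signature, character(1)))]
}

.tree_signature <- function(tree) {
  paste(length(tree$parent),
        paste(tree$parent, collapse = ","),
        paste(substr(tree$kind, 1, 1), collapse = ""),
        paste(vapply(tree$members, function(m) paste(m, collapse = "."),
                     character(1)), collapse = "|"),
        sep = ";")
}

#' @export
print.grouping_tree <- function(x, ...) {
  cat(sprintf("Grouping tree: %d element(s), %d group node(s)\n",
              x$n_elements, x$n_groups))
  for (i in seq_along(x$parent)) {
    lab <- if (x$kind[i] == "element") sprintf("element %d", i)
           else sprintf("group {%s}", paste(x$members[[i]], collapse = ","))
    par <- if (x$parent[i] == 0L) "WORLD" else sprintf("node %d", x$parent[i])
    cat(sprintf("  node %d: %s <- %s\n", i, lab, par))
  }
  invisible(x)
}

#' Enumerate causal structures
#'
#' A causal structure is a grouping tree plus one binary stationarity flag per
#' node: flag 1 means the node's velocity relative to its parent reference
#' frame is nonzero (drawn from the slow-speed Gaussian prior component), flag
#' 0 means it is exactly zero (the delta component). Structures are the
#' cartesian product of each admissible tree with all flag assignments,
#' deduplicated and returned in deterministic canonical order.
#'
#' @inheritParams enumerate_grouping_trees
#' @return list of `causal_structure` objects (fields `tree`, `moving`).
#' @examples
#' length(enumerate_causal_structures(2))  # 12
#' @export
enumerate_causal_structures <- function(n_elements, rules = grammar_rules()) {
  trees <- enumerate_grouping_trees(n_elements, rules)
  out <- list()
  for (t in trees) {
    m <- length(t$parent)
    for (code in 0:(2^m - 1L)) {
      moving <- as.integer(bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L))
      out[[length(out) + 1L]] <-
        structure(list(tree = t, moving = moving), class = "causal_structure")
    }
  }
  sigs <- vapply(out, structure_signature, character(1))
  out <- out[!duplicated(sigs)]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Canonical identity string of a causal structure
#'
#' Two structures are equal iff their trees are isomorphic respecting element
#' labels and their flags agree node-wise; node ordering is canonical by
#' construction so a string signature suffices.
#' @param structure a `causal_structure`.
#' @return character scalar.
#' @export
structure_signature <- function(structure) {
  paste(.tree_signature(structure$tree),
        paste(structure$moving, collapse = ""), sep = "#")
}

#' @export
print.causal_structure <- function(x, ...) {
  cat(sprintf("Causal structure%s over %d element(s)\n",
              if (!is.null(x$id)) sprintf(" #%d", x$id) else "",
              x$tree$n_elements))
  for (i in seq_along(x$tree$parent)) {
    lab <- if (x$tree$kind[i] == "element") sprintf("element %d", i)
           else sprintf("group {%s}", paste(x$tree$members[[i]], collapse = ","))
    cat(sprintf("  %s: %s\n", lab,
                if (x$moving[i] == 1L) "moving" else "stationary"))
  }
  invisible(x)
}

#' Percept-defining node of an element
#'
#' Walks from the element towards the world and returns the first node whose
#' stationarity flag is 1 (nonzero relative velocity); its posterior defines
#' the element's perceived velocity. Returns `0` (stationary) if every node on
#' the path has flag 0, in which case the percept is exactly zero velocity.
#'
#' @param structure a `causal_structure`.
#' @param element element id (leaf index).
#' @return integer node id, or `0L` for a stationary percept.
#' @export
percept_node <- function(structure, element) {
  tree <- structure$tree
  if (!is.numeric(element) || length(element) != 1L ||
      element < 1 || element > tree$n_elements || element != round(element))
    stop(sprintf("unknown element id: %s", paste(element, collapse = ",")))
  for (node in tree$ancestors[[as.integer(element)]])
    if (structure$moving[node] == 1L) return(node)
  0L
}

#' Is a causal structure 'pure'?
#'
#' A structure is pure when every group node has at least one child with
#' stationarity flag 0 (a stationary member anchoring the group's reference
#' frame). Pure structures are the subset used to approximate inference in
#' three-level scenes; structures without group nodes are vacuously pure.
#'
#' @param structure a `causal_structure`.
#' @return logical scalar.
#' @export
is_pure <- function(structure) {
  tree <- structure$tree
  groups <- which(tree$kind == "group")
  for (g in groups) {
    kids <- which(tree$parent == g)
    if (!any(structure$moving[kids] == 0L)) return(FALSE)
  }
  TRUE
}

#' Count causal structures
#'
#' Length of [enumerate_causal_structures()]; the attribute `"bound"` carries
#' the loose upper bound T(n) * 2^(n(n+1)/2) where T(n) is the number of
#' grouping trees and n(n+1)/2 bounds the node count of any tree.
#'
#' @inheritParams enumerate_grouping_trees
#' @return integer count with attribute `bound`.
#' @examples
#' count_causal_structures(3)  # 264
#' @export
count_causal_structures <- function(n_elements, rules = grammar_rules()) {
  trees <- enumerate_grouping_trees(n_elements, rules)
  n <- as.integer(n_elements)
  cnt <- length(enumerate_causal_structures(n, rules))
  structure(cnt, bound = length(trees) * 2^(n * (n + 1) / 2))
}

#' Serialize causal structures to JSON
#'
#' Each structure is written as a parent array (`0` = world), node kinds and
#' the stationarity flag array, which is enough to reconstruct it exactly.
#'
#' @param structures list of `causal_structure` objects.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
structures_to_json <- function(structures, path = NULL) {
  recs <- lapply(structures, function(s) {
    list(n_elements = s$tree$n_elements, parent = s$tree$parent,
         kind = s$tree$kind, moving = s$moving)
  })
  json <- jsonlite::toJSON(recs, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Read causal structures from JSON
#' @param path file path or JSON string produced by [structures_to_json()].
#' @return list of `causal_structure` objects.
#' @export
structures_from_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(recs, function(r) {
    n <- as.integer(r$n_elements)
    parent <- as.integer(unlist(r$parent))
    kind <- as.character(unlist(r$kind))
    members <- vector("list", length(parent))
    for (e in seq_len(n)) members[[e]] <- e
    # recover group memberships from parent links
    for (g in rev(which(kind == "group"))) {
      desc <- integer(0)
      stack <- which(parent == g)
      while (length(stack)) {
        nd <- stack[1]; stack <- stack[-1]
        if (kind[nd] == "element") desc <- c(desc, nd)
        else stack <- c(stack, which(parent == nd))
      }
      members[[g]] <- sort(desc)
    }
    structure(list(tree = new_grouping_tree(n, parent, kind, members),
                   moving = as.integer(unlist(r$moving))),
              class = "causal_structure")
  })
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}
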