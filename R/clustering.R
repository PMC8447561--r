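#' @include cohort.R
NULL

#' Spearman-correlation distance between patient profiles
#'
#' Dissimilarity d(i,j) = 1 - rho(i,j), where rho is the Spearman rank
#' correlation between the two patients' z-scored feature profiles
#' (average ranks for ties). Patients are the columns of \code{z}.
#' Entries lie in [0, 2]: 0 for perfectly concordant profiles, 2 for
#' perfectly anti-monotone ones.
#'
#' @param z numeric feature-by-patient matrix without missing values
#'   (at least 2 features and 2 patients).
#' @return symmetric patient-by-patient distance matrix with zero
#'   diagonal.
#' @export
spearmanDistance <- function(z) {
    if (ncol(z) < 2 || nrow(z) < 2)
        stop("need at least 2 patients and 2 features")
    if (anyNA(z))
        stop("z-matrix must not contain missing values")
    flat <- apply(z, 2, function(v) length(unique(v)) == 1L)
    if (any(flat))
        stop("patient profile(s) with zero rank variance (all features ",
             "tied): ", paste(colnames(z)[flat], collapse = ", "))
    rho <- stats::cor(z, method = "spearman")
    d <- 1 - rho
    d <- pmin(pmax((d + t(d)) / 2, 0), 2)
    diag(d) <- 0
    d
}

## Ward inter-cluster distance update (Lance-Williams, squared-update
## convention): the supplied dissimilarities are treated as the
## singleton-level merge costs and updated as
##   d(k, i+j)^2 = [(n_i+n_k) d(k,i)^2 + (n_j+n_k) d(k,j)^2
##                  - n_k d(i,j)^2] / (n_i+n_j+n_k).
## On Euclidean input this reproduces Ward's minimum-variance criterion
## exactly; on the 1-rho dissimilarity it is the usual heuristic
## generalization.
.wardUpdate <- function(dik, djk, dij, ni, nj, nk) {
    sqrt(pmax(((ni + nk) * dik^2 + (nj + nk) * djk^2 - nk * dij^2) /
                  (ni + nj + nk), 0))
}

## deterministic argmin over the upper triangle: smallest value, ties
## broken by lowest smaller index, then lowest larger index
.minPair <- function(D) {
    n <- nrow(D)
    D[lower.tri(D, diag = TRUE)] <- Inf
    v <- min(D)
    idx <- which(D == v, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    c(idx[1, 1], idx[1, 2], v)
}

#' Ward agglomerative clustering of a dissimilarity matrix
#'
#' Agglomerates patients by Ward's minimum-variance criterion, updating
#' inter-cluster distances with the Lance-Williams recurrence for Ward
#' (squared-update convention) applied to the supplied dissimilarities.
#' Merging is fully deterministic: ties are broken by the lowest
#' smaller-index pair (indices in creation order -- leaves in input
#' order, then merge order), so reruns need no seed.
#'
#' @param d symmetric dissimilarity matrix (e.g. [spearmanDistance()]).
#' @return a \linkS4class{LinkageTree}.
#' @export
wardLinkage <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    if (n < 2) stop("need at least 2 patients to cluster")
    if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0))
        stop("d must be a symmetric dissimilarity matrix with zero diagonal")
    labels <- colnames(d)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    ## active clusters in creation order
    code <- -seq_len(n)         # hclust codes: -leaf or +merge step
    sizes <- rep(1L, n)
    D <- d
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    msize <- integer(n - 1L)
    for (s in seq_len(n - 1L)) {
        mp <- .minPair(D)
        i <- mp[1]; j <- mp[2]
        height[s] <- mp[3]
        pair <- sort(c(code[i], code[j]))
        ## negative (leaf) entries first, each subgroup ascending by age
        merge[s, ] <- c(pair[pair < 0][order(-pair[pair < 0])],
                        pair[pair > 0])
        ni <- sizes[i]; nj <- sizes[j]
        msize[s] <- ni + nj
        others <- setdiff(seq_along(code), c(i, j))
        newd <- .wardUpdate(D[i, others], D[j, others], D[i, j],
                            ni, nj, sizes[others])
        D <- D[others, others, drop = FALSE]
        D <- rbind(cbind(D, newd), c(newd, 0))
        code <- c(code[others], s)
        sizes <- c(sizes[others], ni + nj)
    }
    ord <- .leafOrder(merge)
    new("LinkageTree", merge = merge, height = height, size = msize,
        order = ord, labels = labels)
}

.leafOrder <- function(merge) {
    n <- nrow(merge) + 1L
    sub <- vector("list", n - 1L)
    get <- function(k) if (k < 0) -k else sub[[k]]
    for (s in seq_len(n - 1L))
        sub[[s]] <- c(get(merge[s, 1]), get(merge[s, 2]))
    as.integer(sub[[n - 1L]])
}

#' @rdname asHclust
#' @export
setMethod("asHclust", "LinkageTree", function(x) {
    structure(list(merge = x@merge, height = x@height, order = x@order,
                   labels = x@labels, method = "ward",
                   dist.method = "spearman", call = match.call()),
              class = "hclust")
})

#' Cut a linkage tree into k clusters
#'
#' Removes the k-1 last (highest) merges; patients of each remaining
#' subtree share a cluster, with indices assigned by order of first
#' patient appearance in the cohort.
#'
#' @param tree a \linkS4class{LinkageTree}.
#' @param k number of clusters, 1 <= k <= n.
#' @return a \linkS4class{ClusterAssignment} (unlabelled).
#' @export
cutClusters <- function(tree, k) {
    n <- length(tree@labels)
    if (k < 1 || k > n) stop("k must lie in [1, n]")
    k <- as.integer(k)
    comp <- seq_len(n)
    sub <- vector("list", n - 1L)
    get <- function(m) if (m < 0) -m else sub[[m]]
    nm <- n - k
    for (s in seq_len(n - 1L)) {
        members <- c(get(tree@merge[s, 1]), get(tree@merge[s, 2]))
        sub[[s]] <- members
        if (s <= nm) comp[members] <- min(comp[members])
    }
    cl <- as.integer(factor(comp, levels = unique(comp)))
    new("ClusterAssignment", patientIds = tree@labels, cluster = cl,
        k = k, labels = rep(NA_character_, k))
}

#' Calinski-Harabasz score of a clustering
#'
#' CH = (B/(k-1)) / (W/(n-k)), with between-cluster dispersion
#' B = sum_j n_j ||c_j - c||^2 and within-cluster dispersion
#' W = sum_j sum_i ||x_i - c_j||^2, Euclidean on the z-scored feature
#' space. Larger is better; perfectly compact clusters (W = 0) return
#' +Inf with a warning.
#'
#' @param z feature-by-patient matrix (patients are points).
#' @param assignment a \linkS4class{ClusterAssignment} or an integer
#'   cluster vector over patients.
#' @return CH score (numeric scalar).
#' @export
calinskiHarabasz <- function(z, assignment) {
    cl <- if (is(assignment, "ClusterAssignment")) assignment@cluster
          else as.integer(assignment)
    n <- ncol(z)
    if (length(cl) != n) stop("assignment length must match patients")
    k <- length(unique(cl))
    if (k < 2) stop("CH requires k >= 2")
    if (n <= k) stop("CH requires n > k")
    x <- t(z)
    centroid <- colMeans(x)
    B <- 0; W <- 0
    for (g in unique(cl)) {
        xi <- x[cl == g, , drop = FALSE]
        cg <- colMeans(xi)
        B <- B + nrow(xi) * sum((cg - centroid)^2)
        W <- W + sum(sweep(xi, 2, cg)^2)
    }
    if (W == 0) {
        warning("perfectly compact clusters (W = 0); returning +Inf")
        return(Inf)
    }
    (B / (k - 1)) / (W / (n - k))
}

#' Elbow and Calinski-Harabasz diagnostics over a range of k
#'
#' Within-cluster sum of squares (elbow curve) and CH score per k,
#' computed from cuts of the same linkage tree on the z-scored feature
#' space.
#'
#' @param z feature-by-patient matrix.
#' @param tree a \linkS4class{LinkageTree} over the same patients.
#' @param kRange integer vector of cluster counts within [1, n].
#' @return data.frame(k, withinSS, ch) -- \code{ch} is NA for k < 2 or
#'   k = n.
#' @export
elbowCurve <- function(z, tree, kRange = 1:10) {
    n <- ncol(z)
    kRange <- sort(unique(as.integer(kRange)))
    if (any(kRange < 1 | kRange > n)) stop("kRange must lie within [1, n]")
    x <- t(z)
    res <- lapply(kRange, function(k) {
        cl <- cutClusters(tree, k)@cluster
        W <- sum(vapply(unique(cl), function(g) {
            xi <- x[cl == g, , drop = FALSE]
            sum(sweep(xi, 2, colMeans(xi))^2)
        }, numeric(1)))
        ch <- if (k >= 2 && k < n)
            suppressWarnings(calinskiHarabasz(z, cl)) else NA_real_
        data.frame(k = k, withinSS = W, ch = ch)
    })
    do.call(rbind, res)
}

#' Assign semantic phenotype labels to a 2-cluster cut
#'
#' The cluster with the lower median of the anchor feature (default
#' HDL-C, the top discriminating feature) becomes the
#' \code{hypolipoprotein} cluster, the other the
#' \code{normolipoprotein} cluster. Tied medians fall back to the lower
#' mean, then to the lower cluster index, with a warning -- so labelling
#' is deterministic and independent of dendrogram layout.
#'
#' @param assignment a k = 2 \linkS4class{ClusterAssignment}.
#' @param x the \linkS4class{SepsisCohort} clustered (raw feature values
#'   are used for the anchor medians).
#' @param anchor anchor feature name (default \code{"hdl_c"}).
#' @return the assignment with semantic labels filled in.
#' @export
labelClusters <- function(assignment, x, anchor = "hdl_c") {
    if (assignment@k != 2L)
        stop("semantic labels are defined only for k = 2")
    if (!anchor %in% rownames(x))
        stop("anchor feature '", anchor, "' not present in cohort")
    v <- featureMatrix(x)[anchor, assignment@patientIds]
    med <- vapply(1:2, function(g)
        stats::median(v[assignment@cluster == g], na.rm = TRUE), numeric(1))
    if (med[1] == med[2]) {
        warning("tied anchor medians; breaking tie by lower mean, ",
                "then cluster index")
        mu <- vapply(1:2, function(g)
            mean(v[assignment@cluster == g], na.rm = TRUE), numeric(1))
        hypo <- if (mu[1] == mu[2]) 1L else which.min(mu)
    } else hypo <- which.min(med)
    lab <- rep("normolipoprotein", 2)
    lab[hypo] <- "hypolipoprotein"
    assignment@labels <- lab
    assignment
}

#' Adjusted Rand index by direct pair counting
#'
#' Chance-corrected agreement between two partitions of the same items:
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b partition vectors (any label type) of equal length.
#' @return ARI (numeric scalar).
#' @export
ariScore <- function(a, b) {
    if (length(a) != length(b)) stop("partitions must have equal length")
    tab <- table(a, b)
    n <- sum(tab)
    ch2 <- function(x) sum(choose(x, 2))
    sumnij <- ch2(tab)
    sumai <- ch2(rowSums(tab))
    sumbj <- ch2(colSums(tab))
    expct <- sumai * sumbj / choose(n, 2)
    denom <- (sumai + sumbj) / 2 - expct
    if (denom == 0) return(0)
    (sumnij - expct) / denom
}
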