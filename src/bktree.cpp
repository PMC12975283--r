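#include <Rcpp.h>
#include <vector>
#include <string>
#include <deque>
#include <algorithm>

using namespace Rcpp;

// Hamming distance with N-policy: an N mismatches every base, including N.
// Returns -1 on unequal lengths; the R wrapper decides whether that is an
// error (clustering) or an "other" bucket (divergence statistics).
static inline int hamming_str(const std::string& a, const std::string& b) {
    if (a.size() != b.size()) return -1;
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        const char ca = a[i], cb = b[i];
        if (ca == 'N' || cb == 'N' || ca != cb) ++d;
    }
    return d;
}

// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
    R_xlen_t n = std::max(a.size(), b.size());
    if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
        stop("arguments must have equal length or length one");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
        std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
        out[i] = hamming_str(sa, sb);
    }
    return out;
}

// BK-tree over fixed-length strings under Hamming distance. Children are kept
// as (distance, node) pairs per node; the triangle inequality restricts the
// search to child edges with |d(query, node) - edge| <= k.
struct BKTreeCpp {
    std::vector<std::string> items;
    std::vector<std::vector<std::pair<int, int> > > children;

    void insert(const std::string& s) {
        items.push_back(s);
        children.push_back(std::vector<std::pair<int, int> >());
        int idx = (int)items.size() - 1;
        if (idx == 0) return;
        int node = 0;
        for (;;) {
            int d = hamming_str(s, items[node]);
            if (d < 0) stop("all strings in a BK-tree must have equal length");
            int next = -1;
            for (size_t j = 0; j < children[node].size(); ++j) {
                if (children[node][j].first == d) { next = children[node][j].second; break; }
            }
            if (next < 0) { children[node].push_back(std::make_pair(d, idx)); return; }
            node = next;
        }
    }

    // 0-based indices of items within distance k of q, in insertion order.
    std::vector<int> query(const std::string& q, int k) const {
        std::vector<int> hits;
        if (items.empty()) return hits;
        std::vector<int> stack;
        stack.push_back(0);
        while (!stack.empty()) {
            int node = stack.back(); stack.pop_back();
            int d = hamming_str(q, items[node]);
            if (d < 0) stop("query length differs from indexed strings");
            if (d <= k) hits.push_back(node);
            for (size_t j = 0; j < children[node].size(); ++j) {
                int edge = children[node][j].first;
                if (edge >= d - k && edge <= d + k)
                    stack.push_back(children[node][j].second);
            }
        }
        std::sort(hits.begin(), hits.end());
        return hits;
    }
};


// [[Rcpp::export]]
SEXP bktree_build_cpp(CharacterVector umis) {
    BKTreeCpp* t = new BKTreeCpp();
    for (R_xlen_t i = 0; i < umis.size(); ++i)
        t->insert(as<std::string>(umis[i]));
    XPtr<BKTreeCpp> p(t, true);
    p.attr("class") = "bktree_ptr";
    return p;
}

// [[Rcpp::export]]
IntegerVector bktree_query_cpp(SEXP ptr, std::string q, int k) {
    XPtr<BKTreeCpp> p(ptr);
    std::vector<int> hits = p->query(q, k);
    IntegerVector out(hits.size());
    for (size_t i = 0; i < hits.size(); ++i) out[i] = hits[i] + 1;  // 1-based
    return out;
}

// [[Rcpp::export]]
int bktree_size_cpp(SEXP ptr) {
    XPtr<BKTreeCpp> p(ptr);
    return (int)p->items.size();
}

// UMI cluster assignment. `umis` must already be sorted by descending count
// with ties broken by lexicographic order; that order defines root selection
// and makes the result deterministic. mode: 0 = directional (iterative
// closure, abundance threshold tested against the absorbing member),
// 1 = acyclic (root-adjacent only, threshold tested against the root).
// A neighbor v is absorbed by member u when count(u) >= mult*count(v) - 1.
// [[Rcpp::export]]
IntegerVector cluster_umis_cpp(CharacterVector umis, IntegerVector counts,
                               int maxEdits, double mult, int mode) {
    int n = umis.size();
    IntegerVector membership(n, 0);
    if (n == 0) return membership;

    BKTreeCpp tree;
    std::vector<std::string> sv(n);
    for (int i = 0; i < n; ++i) {
        sv[i] = as<std::string>(umis[i]);
        tree.insert(sv[i]);
    }

    int cid = 0;
    for (int i = 0; i < n; ++i) {
        if (membership[i] != 0) continue;
        membership[i] = ++cid;
        if (mode == 1) {  // acyclic: direct neighbors of the root only
            std::vector<int> nb = tree.query(sv[i], maxEdits);
            for (size_t j = 0; j < nb.size(); ++j) {
                int v = nb[j];
                if (membership[v] != 0) continue;
                if ((double)counts[i] >= mult * (double)counts[v] - 1.0 - 1e-9)
                    membership[v] = cid;
            }
        } else {          // directional: breadth-first transitive closure
            std::deque<int> frontier;
            frontier.push_back(i);
            while (!frontier.empty()) {
                int u = frontier.front(); frontier.pop_front();
                std::vector<int> nb = tree.query(sv[u], maxEdits);
                for (size_t j = 0; j < nb.size(); ++j) {
                    int v = nb[j];
                    if (membership[v] != 0) continue;
                    if ((double)counts[u] >= mult * (double)counts[v] - 1.0 - 1e-9) {
                        membership[v] = cid;
                        frontier.push_back(v);
                    }
                }
            }
        }
    }
    return membership;
}
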