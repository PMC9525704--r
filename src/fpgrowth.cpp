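// FP-Growth mining and rule generation kernels. Transactions arrive as
// integer vectors of item ranks (1-based, sorted ascending = descending
// global support); the recursion mirrors conditional-pattern-base mining on
// the rank-ordered prefix tree.

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

namespace {

struct Miner {
  int n_items;
  int max_len;
  double min_count;
  std::vector<int> flat;        // concatenated itemsets (ranks)
  std::vector<int> sizes;       // itemset lengths
  std::vector<double> counts;   // support counts

  void emit(const std::vector<int> &suffix, double cnt) {
    flat.insert(flat.end(), suffix.begin(), suffix.end());
    sizes.push_back((int)suffix.size());
    counts.push_back(cnt);
  }

  // paths: conditional branches (strictly increasing rank vectors); w: branch
  // weights. suffix holds the items conditioned on so far.
  void mine(const std::vector<std::vector<int>> &paths,
            const std::vector<double> &w, std::vector<int> &suffix) {
    std::vector<double> tab(n_items + 1, 0.0);
    for (size_t b = 0; b < paths.size(); ++b)
      for (int it : paths[b]) tab[it] += w[b];
    for (int i = n_items; i >= 1; --i) {
      if (tab[i] < min_count) continue;
      suffix.push_back(i);
      emit(suffix, tab[i]);
      if ((int)suffix.size() < max_len) {
        std::vector<std::vector<int>> cond;
        std::vector<double> cw;
        for (size_t b = 0; b < paths.size(); ++b) {
          const std::vector<int> &p = paths[b];
          size_t pos = std::lower_bound(p.begin(), p.end(), i) - p.begin();
          if (pos < p.size() && p[pos] == i && pos > 0) {
            cond.emplace_back(p.begin(), p.begin() + pos);
            cw.push_back(w[b]);
          }
        }
        if (!cond.empty()) mine(cond, cw, suffix);
      }
      suffix.pop_back();
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".fpg_mine")]]
List fpg_mine(List transactions, int n_items, double min_count, int max_len,
              IntegerVector focus_ranks) {
  std::vector<std::vector<int>> paths;
  std::vector<double> w;
  // merge identical branches (the FP-tree's prefix compression)
  std::map<std::vector<int>, double> branch;
  for (R_xlen_t t = 0; t < transactions.size(); ++t) {
    IntegerVector tr = transactions[t];
    if (tr.size() == 0) continue;
    branch[std::vector<int>(tr.begin(), tr.end())] += 1.0;
  }
  for (auto &kv : branch) {
    paths.push_back(kv.first);
    w.push_back(kv.second);
  }

  Miner m;
  m.n_items = n_items;
  m.max_len = max_len;
  m.min_count = min_count;
  std::vector<int> suffix;

  if (focus_ranks.size() == 0) {
    m.mine(paths, w, suffix);
  } else {
    std::vector<double> tab(n_items + 1, 0.0);
    for (size_t b = 0; b < paths.size(); ++b)
      for (int it : paths[b]) tab[it] += w[b];
    std::vector<int> foc(focus_ranks.begin(), focus_ranks.end());
    std::sort(foc.rbegin(), foc.rend());
    for (int f : foc) {
      if (tab[f] < m.min_count) continue;
      suffix.push_back(f);
      m.emit(suffix, tab[f]);
      if (max_len > 1) {
        std::vector<std::vector<int>> cond;
        std::vector<double> cw;
        for (size_t b = 0; b < paths.size(); ++b) {
          const std::vector<int> &p = paths[b];
          size_t pos = std::lower_bound(p.begin(), p.end(), f) - p.begin();
          if (pos < p.size() && p[pos] == f && pos > 0) {
            cond.emplace_back(p.begin(), p.begin() + pos);
            cw.push_back(w[b]);
          }
        }
        if (!cond.empty()) m.mine(cond, cw, suffix);
      }
      suffix.pop_back();
    }
  }

  return List::create(_["flat"] = wrap(m.flat), _["sizes"] = wrap(m.sizes),
                      _["counts"] = wrap(m.counts));
}

static double subset_count(const std::vector<int> &items,
                           const std::vector<std::vector<int>> &tidlists,
                           std::map<std::vector<int>, double> &cache) {
  auto hit = cache.find(items);
  if (hit != cache.end()) return hit->second;
  // intersect the (sorted) transaction-id lists of the items
  std::vector<int> cur = tidlists[items[0] - 1];
  for (size_t k = 1; k < items.size() && !cur.empty(); ++k) {
    const std::vector<int> &nxt = tidlists[items[k] - 1];
    std::vector<int> out;
    std::set_intersection(cur.begin(), cur.end(), nxt.begin(), nxt.end(),
                          std::back_inserter(out));
    cur.swap(out);
  }
  double cnt = (double)cur.size();
  cache[items] = cnt;
  return cnt;
}

// itemsets: flat/sizes/counts from fpg_mine (item ids, any consistent
// coding); tid_list: per-item sorted transaction indices; consequent_ok:
// logical per item. Returns flat rule arrays.
// [[Rcpp::export(name = ".fpg_rules")]]
List fpg_rules(IntegerVector flat, IntegerVector sizes, NumericVector counts,
               List tid_list, int n_trans, double min_lift,
               LogicalVector consequent_ok) {
  int n_items = tid_list.size();
  std::vector<std::vector<int>> tidlists(n_items);
  for (int i = 0; i < n_items; ++i) {
    IntegerVector v = tid_list[i];
    tidlists[i].assign(v.begin(), v.end());
  }
  std::map<std::vector<int>, double> cache;
  // seed the cache with every mined itemset
  {
    size_t off = 0;
    for (R_xlen_t s = 0; s < sizes.size(); ++s) {
      std::vector<int> set(flat.begin() + off, flat.begin() + off + sizes[s]);
      std::sort(set.begin(), set.end());
      cache[set] = counts[s];
      off += sizes[s];
    }
  }

  std::vector<int> a_flat, a_sizes, c_flat, c_sizes;
  std::vector<double> sup, conf, lift;

  size_t off = 0;
  for (R_xlen_t s = 0; s < sizes.size(); ++s) {
    int m = sizes[s];
    if (m < 2) { off += m; continue; }
    std::vector<int> set(flat.begin() + off, flat.begin() + off + m);
    std::sort(set.begin(), set.end());
    double joint = counts[s];
    for (int mask = 1; mask < (1 << m) - 1; ++mask) {
      std::vector<int> ante, cons;
      bool ok = true;
      for (int b = 0; b < m; ++b) {
        if (mask & (1 << b)) {
          if (!consequent_ok[set[b] - 1]) { ok = false; break; }
          cons.push_back(set[b]);
        } else {
          ante.push_back(set[b]);
        }
      }
      if (!ok) continue;
      double sup_a = subset_count(ante, tidlists, cache);
      double sup_c = subset_count(cons, tidlists, cache);
      double confidence = joint / sup_a;
      double lft = confidence / (sup_c / n_trans);
      if (lft >= min_lift) {
        a_flat.insert(a_flat.end(), ante.begin(), ante.end());
        a_sizes.push_back((int)ante.size());
        c_flat.insert(c_flat.end(), cons.begin(), cons.end());
        c_sizes.push_back((int)cons.size());
        sup.push_back(joint / n_trans);
        conf.push_back(confidence);
        lift.push_back(lft);
      }
    }
    off += m;
  }

  return List::create(
      _["a_flat"] = wrap(a_flat), _["a_sizes"] = wrap(a_sizes),
      _["c_flat"] = wrap(c_flat), _["c_sizes"] = wrap(c_sizes),
      _["support"] = wrap(sup), _["confidence"] = wrap(conf),
      _["lift"] = wrap(lift));
}
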