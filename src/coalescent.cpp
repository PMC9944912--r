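// Structured-coalescent simulator for the island-model neutral null.
//
// Demes exchange migrants symmetrically; in the hierarchical variant demes
// are nested in groups with a lower between-group migration rate. One
// genealogy is simulated per locus for the sampled allele copies
// (coalescence rate 1 per lineage pair within a deme, time in units of 2N
// generations per deme; per-lineage migration rates mig_within/2 and
// mig_between/2), and a single mutation is placed uniformly on the tree,
// which always yields a polymorphic sample. Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".coal_island_counts")]]
IntegerMatrix coal_island_counts(int n_sims,
                                 IntegerVector sample_sizes,
                                 IntegerVector sample_group,
                                 int n_groups,
                                 int demes_per_group,
                                 double mig_within,
                                 double mig_between) {
  const int n_pops = sample_sizes.size();
  const int n_demes = n_groups * demes_per_group;
  if (n_groups == 1) mig_between = 0.0;
  int n_tips = 0;
  for (int p = 0; p < n_pops; ++p) n_tips += 2 * sample_sizes[p];
  if (n_tips < 2) stop("need at least two sampled allele copies");

  // place sampled pops in distinct demes of their group
  std::vector<int> pop_deme(n_pops);
  std::vector<int> used_in_group(n_groups, 0);
  for (int p = 0; p < n_pops; ++p) {
    int g = sample_group[p] - 1;
    if (g < 0 || g >= n_groups) stop("sample_group out of range");
    if (used_in_group[g] >= demes_per_group)
      stop("more sampled populations than demes in a group");
    pop_deme[p] = g * demes_per_group + used_in_group[g]++;
  }

  const int n_nodes = 2 * n_tips - 1;
  std::vector<double> node_time(n_nodes);
  std::vector<int> child1(n_nodes), child2(n_nodes);
  std::vector<int> tip_pop(n_tips);
  {
    int t = 0;
    for (int p = 0; p < n_pops; ++p)
      for (int i = 0; i < 2 * sample_sizes[p]; ++i) tip_pop[t++] = p;
  }

  IntegerMatrix out(n_sims, 2 * n_pops);
  std::vector<int> count(n_demes);
  std::vector<std::vector<int>> members(n_demes);
  std::vector<int> lin_node, lin_deme, lin_slot;
  std::vector<int> derived(n_tips);
  std::vector<int> stack;
  std::vector<int> parent;
  if (demes_per_group == 1) mig_within = 0.0;  // no within-group target exists

  for (int s = 0; s < n_sims; ++s) {
    // init
    std::fill(count.begin(), count.end(), 0);
    for (int d = 0; d < n_demes; ++d) members[d].clear();
    lin_node.clear(); lin_deme.clear(); lin_slot.clear();
    for (int t = 0; t < n_tips; ++t) {
      int d = pop_deme[tip_pop[t]];
      lin_node.push_back(t);
      lin_deme.push_back(d);
      lin_slot.push_back(members[d].size());
      members[d].push_back(t);  // stores lineage index == t initially
      node_time[t] = 0.0;
      count[d]++;
    }
    // members[d] holds *lineage indices* into lin_* arrays
    for (int d = 0; d < n_demes; ++d)
      for (size_t k = 0; k < members[d].size(); ++k)
        lin_slot[members[d][k]] = k;

    double sumpairs = 0.0;
    for (int d = 0; d < n_demes; ++d)
      sumpairs += 0.5 * count[d] * (count[d] - 1);

    std::vector<int> active(n_tips);
    for (int t = 0; t < n_tips; ++t) active[t] = t;  // active lineage ids
    int n_act = n_tips;
    int next_node = n_tips;
    double now = 0.0;
    double mig_rate_per_lin = 0.5 * (mig_within + mig_between);

    while (n_act > 1) {
      double rate_mig = n_act * mig_rate_per_lin;
      double total = rate_mig + sumpairs;
      now += R::exp_rand() / total;
      if (unif_rand() * total < rate_mig) {
        // migration: uniform lineage, choose destination deme
        int ai = (int)(unif_rand() * n_act); if (ai == n_act) ai--;
        int li = active[ai];
        int d = lin_deme[li];
        int g = d / demes_per_group;
        int dest;
        if (mig_between > 0.0 &&
            unif_rand() * (mig_within + mig_between) >= mig_within) {
          // another group, uniform deme there
          int og = (int)(unif_rand() * (n_groups - 1)); if (og == n_groups - 1) og--;
          if (og >= g) og++;
          int dd = (int)(unif_rand() * demes_per_group);
          if (dd == demes_per_group) dd--;
          dest = og * demes_per_group + dd;
        } else {
          int dd = (int)(unif_rand() * (demes_per_group - 1));
          if (dd == demes_per_group - 1) dd--;
          int local = d - g * demes_per_group;
          if (dd >= local) dd++;
          dest = g * demes_per_group + dd;
        }
        // move lineage li from d to dest
        sumpairs += -(count[d] - 1) + count[dest];
        int slot = lin_slot[li];
        int last = members[d].back();
        members[d][slot] = last; lin_slot[last] = slot;
        members[d].pop_back();
        count[d]--;
        lin_deme[li] = dest;
        lin_slot[li] = members[dest].size();
        members[dest].push_back(li);
        count[dest]++;
      } else {
        // coalescence: pick deme with prob proportional to k(k-1)/2
        double u = unif_rand() * sumpairs;
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < n_demes; ++dd) {
          if (count[dd] > 1) {
            acc += 0.5 * count[dd] * (count[dd] - 1);
            if (u <= acc) { d = dd; break; }
          }
        }
        if (d < 0) { for (int dd = n_demes - 1; dd >= 0; --dd) if (count[dd] > 1) { d = dd; break; } }
        int k = count[d];
        int i1 = (int)(unif_rand() * k); if (i1 == k) i1--;
        int i2 = (int)(unif_rand() * (k - 1)); if (i2 == k - 1) i2--;
        if (i2 >= i1) i2++;
        int la = members[d][i1], lb = members[d][i2];
        int node = next_node++;
        node_time[node] = now;
        child1[node] = lin_node[la];
        child2[node] = lin_node[lb];
        // remove lb (swap-remove), reuse la's slot for merged lineage
        int slot_b = lin_slot[lb];
        int last = members[d].back();
        members[d][slot_b] = last; lin_slot[last] = slot_b;
        members[d].pop_back();
        count[d]--;
        sumpairs -= (count[d]);
        lin_node[la] = node;
        // remove lb from active list
        int bi = -1;
        for (int a = 0; a < n_act; ++a) if (active[a] == lb) { bi = a; break; }
        active[bi] = active[n_act - 1];
        n_act--;
      }
    }

    // mutation uniform on total branch length
    int root = next_node - 1;
    parent.assign(n_nodes, -1);
    for (int v = n_tips; v < n_nodes; ++v) {
      parent[child1[v]] = v;
      parent[child2[v]] = v;
    }
    double L = 0.0;
    for (int v = 0; v < root; ++v) L += node_time[parent[v]] - node_time[v];
    double u = unif_rand() * L;
    int mut_node = root - 1;
    double acc2 = 0.0;
    for (int v = 0; v < root; ++v) {
      acc2 += node_time[parent[v]] - node_time[v];
      if (u <= acc2) { mut_node = v; break; }
    }
    // derived tips = tips below mut_node
    std::fill(derived.begin(), derived.end(), 0);
    stack.clear();
    stack.push_back(mut_node);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v < n_tips) derived[v] = 1;
      else { stack.push_back(child1[v]); stack.push_back(child2[v]); }
    }
    // per-pop derived-allele and heterozygote counts
    for (int p = 0; p < n_pops; ++p) { out(s, p) = 0; out(s, n_pops + p) = 0; }
    int t = 0;
    for (int p = 0; p < n_pops; ++p) {
      for (int i = 0; i < sample_sizes[p]; ++i) {
        int a = derived[t], b = derived[t + 1];
        t += 2;
        out(s, p) += a + b;
        if (a != b) out(s, n_pops + p) += 1;
      }
    }
  }
  return out;
}
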