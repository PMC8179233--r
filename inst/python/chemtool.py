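"""Batch RDKit helper for the ocscreen R package.

Reads one JSON request on stdin, writes one JSON response on stdout.
Ops: canonicalize, smarts_match, fingerprint, ring_info, tanimoto_ref, umap_embed.
Kept dependency-minimal: rdkit + stdlib (numpy/umap only for umap_embed).
"""
import json
import sys


def _mols(smiles):
    from rdkit import Chem
    out = []
    for s in smiles:
        m = Chem.MolFromSmiles(s) if s else None
        out.append(m)
    return out


def op_canonicalize(req):
    from rdkit import Chem
    res = []
    for m in _mols(req["smiles"]):
        res.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"canonical": res}


def op_smarts_match(req):
    from rdkit import Chem
    pats = []
    for p in req["patterns"]:
        q = Chem.MolFromSmarts(p)
        if q is None:
            return {"error": "invalid SMARTS: %s" % p}
        pats.append(q)
    matches = []
    for m in _mols(req["smiles"]):
        if m is None:
            matches.append(None)
        else:
            matches.append(bool(any(m.HasSubstructMatch(q) for q in pats)))
    return {"match": matches}


def op_fingerprint(req):
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(req.get("radius", 2)), fpSize=int(req.get("nbits", 1024)))
    bits = []
    for m in _mols(req["smiles"]):
        if m is None:
            bits.append(None)
        else:
            fp = gen.GetFingerprint(m)
            bits.append(list(fp.GetOnBits()))
    return {"onbits": bits, "nbits": int(req.get("nbits", 1024))}


def op_ring_info(req):
    from rdkit import Chem
    rows = []
    for m in _mols(req["smiles"]):
        if m is None:
            rows.append(None)
            continue
        ri = m.GetRingInfo()
        ring_atoms = set(a for ring in ri.AtomRings() for a in ring)
        n_arom_rings = 0
        for ring in ri.AtomRings():
            if all(m.GetAtomWithIdx(a).GetIsAromatic() for a in ring):
                n_arom_rings += 1
        attach = 0
        for a in ring_atoms:
            for nb in m.GetAtomWithIdx(a).GetNeighbors():
                if nb.GetIdx() not in ring_atoms:
                    attach += 1
        hetero = any(at.GetAtomicNum() not in (1, 6) for at in m.GetAtoms())
        rows.append({
            "n_rings": ri.NumRings(),
            "n_aromatic_rings": n_arom_rings,
            "heavy_atoms": m.GetNumHeavyAtoms(),
            "n_substituents": attach,
            "has_heteroatom": bool(hetero),
        })
    return {"info": rows}


def op_tanimoto_ref(req):
    """Tanimoto similarity of each molecule to a single reference SMILES."""
    from rdkit import Chem, DataStructs
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(req.get("radius", 2)), fpSize=int(req.get("nbits", 1024)))
    ref = Chem.MolFromSmiles(req["reference"])
    if ref is None:
        return {"error": "invalid reference SMILES"}
    rfp = gen.GetFingerprint(ref)
    sims = []
    for m in _mols(req["smiles"]):
        sims.append(None if m is None else
                    DataStructs.TanimotoSimilarity(rfp, gen.GetFingerprint(m)))
    return {"similarity": sims}


def op_umap_embed(req):
    import numpy as np
    import umap
    x = np.asarray(req["matrix"], dtype=float)
    em = umap.UMAP(n_neighbors=int(req.get("n_neighbours", 15)),
                   min_dist=float(req.get("min_dist", 0.1)),
                   metric="euclidean",
                   random_state=int(req.get("seed", 0)))
    y = em.fit_transform(x)
    return {"coords": y.tolist()}


OPS = {
    "canonicalize": op_canonicalize,
    "smarts_match": op_smarts_match,
    "fingerprint": op_fingerprint,
    "ring_info": op_ring_info,
    "tanimoto_ref": op_tanimoto_ref,
    "umap_embed": op_umap_embed,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"error": "unknown op: %r" % op}, sys.stdout)
        return
    try:
        json.dump(OPS[op](req), sys.stdout)
    except Exception as exc:  # surface as data, not a crash
        json.dump({"error": str(exc)}, sys.stdout)


if __name__ == "__main__":
    main()
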