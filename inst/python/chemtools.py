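"""Batched cheminformatics backend.

Reads a JSON request {"op": ..., ...} from argv[1], writes a JSON response
to argv[2].  Every op is vectorised over molecules so one process start
services an arbitrarily large batch.  All heavy lifting is delegated to
RDKit; this file contains no science of its own.
"""

import json
import os
import re
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, BRICS, Crippen, Descriptors, QED, RDConfig, rdMolDescriptors
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

ORGANIC = {"B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I", "H"}
BOND_TYPES = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE, 3: Chem.BondType.TRIPLE}

_uncharger = rdMolStandardize.Uncharger()


def _mol(smiles):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles)


def op_ping(req):
    return {"pong": True}


def op_canonical(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        out.append(Chem.MolToSmiles(m) if m is not None else None)
    return {"smiles": out}


def op_standardize(req):
    """Largest organic component, neutralize charges, canonicalize."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "reason": "unparsable"})
            continue
        frags = Chem.GetMolFrags(m, asMols=True, sanitizeFrags=False)
        frags = sorted(frags, key=lambda f: f.GetNumHeavyAtoms(), reverse=True)
        largest = frags[0]
        if any(a.GetSymbol() not in ORGANIC for a in largest.GetAtoms()):
            out.append({"ok": False, "reason": "metal"})
            continue
        try:
            Chem.SanitizeMol(largest)
            neutral = _uncharger.uncharge(largest)
            Chem.SanitizeMol(neutral)
        except Exception as exc:  # pragma: no cover - rare sanitize failure
            out.append({"ok": False, "reason": "sanitize: %s" % exc})
            continue
        charged = Chem.GetFormalCharge(neutral) != 0
        out.append({"ok": True, "smiles": Chem.MolToSmiles(neutral),
                    "charged": bool(charged)})
    return {"records": out}


def _strip_dummies(leaf_smiles):
    """Replace attachment dummies with hydrogens (keeps aromatic N happy)."""
    capped = re.sub(r"\[\d*\*\]", "[H]", leaf_smiles)
    m = Chem.MolFromSmiles(capped)
    if m is None:
        return None
    return Chem.RemoveHs(m)


def op_brics(req):
    """BRICS leaf fragments with attachment dummies stripped and H-capped."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        leaves = BRICS.BRICSDecompose(m)
        frags = []
        for leaf in leaves:
            fm = _strip_dummies(leaf)
            if fm is None or fm.GetNumHeavyAtoms() == 0:
                continue
            frags.append({"smiles": Chem.MolToSmiles(fm),
                          "heavy": fm.GetNumHeavyAtoms()})
        if not frags:
            frags = [{"smiles": Chem.MolToSmiles(m), "heavy": m.GetNumHeavyAtoms()}]
        out.append(frags)
    return {"fragments": out}


def _atom_token(atom):
    sym = atom.GetSymbol()
    chg = atom.GetFormalCharge()
    if chg > 0:
        sym += "+" * chg
    elif chg < 0:
        sym += "-" * (-chg)
    return sym


def op_mol_graph(req):
    """Kekulized atom/bond tables plus canonical atom ranks."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "reason": "unparsable"})
            continue
        mk = Chem.Mol(m)
        try:
            Chem.Kekulize(mk, clearAromaticFlags=True)
        except Exception:
            out.append({"ok": False, "reason": "unkekulizable"})
            continue
        atoms = [_atom_token(a) for a in mk.GetAtoms()]
        bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx(),
                  int(b.GetBondTypeAsDouble())] for b in mk.GetBonds()]
        ranks = list(Chem.CanonicalRankAtoms(m))
        out.append({"ok": True, "atoms": atoms, "bonds": bonds, "ranks": ranks,
                    "canonical": Chem.MolToSmiles(m)})
    return {"graphs": out}


def _atom_from_token(tok):
    sym = tok.rstrip("+-")
    chg = tok.count("+") - tok.count("-")
    a = Chem.Atom(sym)
    a.SetFormalCharge(chg)
    return a


def op_mol_from_graph(req):
    """Assemble atoms+bonds, sanitize (aromaticity re-perceived), canonical SMILES."""
    out = []
    for g in req["graphs"]:
        try:
            rw = Chem.RWMol()
            for tok in g["atoms"]:
                rw.AddAtom(_atom_from_token(tok))
            for i, j, o in g.get("bonds", []):
                rw.AddBond(int(i), int(j), BOND_TYPES[int(o)])
            m = rw.GetMol()
            Chem.SanitizeMol(m)
            out.append({"ok": True, "smiles": Chem.MolToSmiles(m)})
        except Exception as exc:
            out.append({"ok": False, "reason": str(exc)})
    return {"molecules": out}


def _disjoint_maps(mol, frag_mols):
    """Disjoint substructure placement of fragments onto mol atoms.

    Backtracks over the candidate matches of each fragment, since a
    symmetric molecule may offer several placements of one fragment of
    which only some leave room for the others.
    """
    cand = [mol.GetSubstructMatches(fm, uniquify=True, maxMatches=256)
            for fm in frag_mols]
    if any(len(c) == 0 for c in cand):
        return None
    maps = [None] * len(frag_mols)

    def place(i, used):
        if i == len(cand):
            return True
        for match in cand[i]:
            if used.isdisjoint(match):
                maps[i] = list(match)
                if place(i + 1, used | set(match)):
                    return True
        return False

    return maps if place(0, set()) else None


def op_frag_map(req):
    """Atom index sets of each fragment inside its molecule (disjoint)."""
    out = []
    for item in req["items"]:
        m = _mol(item["mol"])
        if m is None:
            out.append(None)
            continue
        fms = [_mol(f) for f in item["frags"]]
        if any(f is None for f in fms):
            out.append(None)
            continue
        maps = _disjoint_maps(m, fms)
        if maps is None:
            mk = Chem.Mol(m)
            try:
                Chem.Kekulize(mk, clearAromaticFlags=True)
                maps = _disjoint_maps(mk, fms)
            except Exception:
                maps = None
        out.append(maps)
    return {"maps": out}


def op_match(req):
    """Does the molecule contain every fragment of the scaffold?

    Matching runs on the aromatic-perceived form only, so a scaffold bond
    that aromatized while the molecule grew around it no longer matches
    (the kekulization mismatch is reported, not papered over).
    """
    out = []
    for item in req["items"]:
        m = _mol(item["mol"])
        if m is None:
            out.append(False)
            continue
        ok = True
        for f in item["frags"]:
            fm = _mol(f)
            if fm is None or not m.HasSubstructMatch(fm):
                ok = False
                break
        out.append(bool(ok))
    return {"match": out}


def _physchem(m):
    return [
        Descriptors.MolWt(m),
        Crippen.MolLogP(m),
        rdMolDescriptors.CalcNumHBA(m),
        rdMolDescriptors.CalcNumHBD(m),
        rdMolDescriptors.CalcNumRotatableBonds(m),
        rdMolDescriptors.CalcNumAmideBonds(m),
        rdMolDescriptors.CalcNumBridgeheadAtoms(m),
        rdMolDescriptors.CalcNumHeteroatoms(m),
        rdMolDescriptors.CalcNumSpiroAtoms(m),
        m.GetNumHeavyAtoms(),
        rdMolDescriptors.CalcFractionCSP3(m),
        rdMolDescriptors.CalcNumAliphaticRings(m),
        rdMolDescriptors.CalcNumSaturatedRings(m),
        rdMolDescriptors.CalcNumRings(m),
        rdMolDescriptors.CalcNumAromaticRings(m),
        rdMolDescriptors.CalcNumHeterocycles(m),
        Descriptors.NumValenceElectrons(m),
        rdMolDescriptors.CalcTPSA(m),
        Crippen.MolMR(m),
    ]


def op_descriptors(req):
    """2048-bit ECFP6 (on-bit indices, 0-based) + 19 physchem descriptors."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(m, 3, nBits=2048)
        out.append({"bits": sorted(fp.GetOnBits()), "physchem": _physchem(m)})
    return {"descriptors": out}


def op_ecfp6(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        fp = AllChem.GetMorganFingerprintAsBitVect(m, 3, nBits=2048)
        out.append(sorted(fp.GetOnBits()))
    return {"bits": out}


def op_score(req):
    """QED drug-likeness and synthetic-accessibility score."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        out.append({"qed": QED.qed(m), "sa": sascorer.calculateScore(m)})
    return {"scores": out}


OPS = {name[3:]: fn for name, fn in list(globals().items())
       if name.startswith("op_")}


def serve(port_file):
    """Line-oriented JSON server on an OS-assigned localhost port.

    The chosen port is written to `port_file` once the socket listens.
    One JSON request per line; one JSON response per line.  Exits when the
    client disconnects.
    """
    import socket
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.bind(("127.0.0.1", 0))
    srv.listen(1)
    with open(port_file, "w") as fh:
        fh.write(str(srv.getsockname()[1]))
    conn, _ = srv.accept()
    rfile = conn.makefile("r", encoding="utf-8")
    wfile = conn.makefile("w", encoding="utf-8")
    for line in rfile:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            if req.get("op") == "quit":
                break
            res = OPS[req["op"]](req)
        except Exception as exc:
            res = {"server_error": str(exc)}
        wfile.write(json.dumps(res) + "\n")
        wfile.flush()
    conn.close()


def main():
    if sys.argv[1] == "--serve":
        serve(sys.argv[2])
        return
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = req.get("op")
    if op not in OPS:
        raise SystemExit("unknown op: %r" % op)
    res = OPS[op](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
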