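<?xml version="1.0"?>
<pathway name="path:demo01" org="hsa" title="Demo signalling pathway">
  <entry id="1" name="hsa:10" type="gene"/>
  <entry id="2" name="hsa:20 hsa:21" type="gene"/>
  <entry id="3" name="hsa:30" type="gene"/>
  <entry id="4" name="hsa:40" type="gene"/>
  <entry id="9" name="cpd:C00001" type="compound"/>
  <entry id="5" type="group">
    <component id="3"/>
    <component id="4"/>
  </entry>
  <relation entry1="1" entry2="2" type="PPrel">
    <subtype name="activation" value="--&gt;"/>
  </relation>
  <relation entry1="2" entry2="3" type="PPrel">
    <subtype name="inhibition" value="--|"/>
    <subtype name="phosphorylation" value="+p"/>
  </relation>
</pathway>
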