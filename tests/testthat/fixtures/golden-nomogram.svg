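<?xml version="1.0" encoding="UTF-8"?>
<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="840" height="290" viewBox="0 0 840 290">
<title>toy nomogram</title>
<style>text{font-family:sans-serif;font-size:11px;} .lab{font-size:12px;font-weight:bold;} .tick{stroke:#000;stroke-width:1;} .ruler{stroke:#000;stroke-width:1.2;}</style>
<text class="lab" x="10.000" y="44.000">Points</text>
<line class="ruler" x1="170.000" y1="40.000" x2="800.000" y2="40.000"/>
<line class="tick" x1="170.000" y1="40.000" x2="170.000" y2="34.000"/>
<text x="170.000" y="31.000" text-anchor="middle">0</text>
<line class="tick" x1="233.000" y1="40.000" x2="233.000" y2="34.000"/>
<text x="233.000" y="31.000" text-anchor="middle">10</text>
<line class="tick" x1="296.000" y1="40.000" x2="296.000" y2="34.000"/>
<text x="296.000" y="31.000" text-anchor="middle">20</text>
<line class="tick" x1="359.000" y1="40.000" x2="359.000" y2="34.000"/>
<text x="359.000" y="31.000" text-anchor="middle">30</text>
<line class="tick" x1="422.000" y1="40.000" x2="422.000" y2="34.000"/>
<text x="422.000" y="31.000" text-anchor="middle">40</text>
<line class="tick" x1="485.000" y1="40.000" x2="485.000" y2="34.000"/>
<text x="485.000" y="31.000" text-anchor="middle">50</text>
<line class="tick" x1="548.000" y1="40.000" x2="548.000" y2="34.000"/>
<text x="548.000" y="31.000" text-anchor="middle">60</text>
<line class="tick" x1="611.000" y1="40.000" x2="611.000" y2="34.000"/>
<text x="611.000" y="31.000" text-anchor="middle">70</text>
<line class="tick" x1="674.000" y1="40.000" x2="674.000" y2="34.000"/>
<text x="674.000" y="31.000" text-anchor="middle">80</text>
<line class="tick" x1="737.000" y1="40.000" x2="737.000" y2="34.000"/>
<text x="737.000" y="31.000" text-anchor="middle">90</text>
<line class="tick" x1="800.000" y1="40.000" x2="800.000" y2="34.000"/>
<text x="800.000" y="31.000" text-anchor="middle">100</text>
<text class="lab" x="10.000" y="90.000">x</text>
<line class="ruler" x1="170.000" y1="86.000" x2="800.000" y2="86.000"/>
<line class="tick" x1="170.000" y1="86.000" x2="170.000" y2="80.000"/>
<text x="170.000" y="77.000" text-anchor="middle">1</text>
<line class="tick" x1="240.000" y1="86.000" x2="240.000" y2="80.000"/>
<text x="240.000" y="77.000" text-anchor="middle">2</text>
<line class="tick" x1="380.000" y1="86.000" x2="380.000" y2="80.000"/>
<text x="380.000" y="77.000" text-anchor="middle">4</text>
<line class="tick" x1="520.000" y1="86.000" x2="520.000" y2="80.000"/>
<text x="520.000" y="77.000" text-anchor="middle">6</text>
<line class="tick" x1="660.000" y1="86.000" x2="660.000" y2="80.000"/>
<text x="660.000" y="77.000" text-anchor="middle">8</text>
<line class="tick" x1="800.000" y1="86.000" x2="800.000" y2="80.000"/>
<text x="800.000" y="77.000" text-anchor="middle">10</text>
<text class="lab" x="10.000" y="136.000">f</text>
<line class="ruler" x1="170.000" y1="132.000" x2="256.800" y2="132.000"/>
<line class="tick" x1="170.000" y1="132.000" x2="170.000" y2="126.000"/>
<text x="170.000" y="123.000" text-anchor="middle">ctl</text>
<line class="tick" x1="256.800" y1="132.000" x2="256.800" y2="126.000"/>
<text x="256.800" y="123.000" text-anchor="middle">trt</text>
<text class="lab" x="10.000" y="182.000">Total points</text>
<line class="ruler" x1="170.000" y1="178.000" x2="800.000" y2="178.000"/>
<line class="tick" x1="170.000" y1="178.000" x2="170.000" y2="172.000"/>
<text x="170.000" y="169.000" text-anchor="middle">0</text>
<line class="tick" x1="225.371" y1="178.000" x2="225.371" y2="172.000"/>
<text x="225.371" y="169.000" text-anchor="middle">10</text>
<line class="tick" x1="280.742" y1="178.000" x2="280.742" y2="172.000"/>
<text x="280.742" y="169.000" text-anchor="middle">20</text>
<line class="tick" x1="336.113" y1="178.000" x2="336.113" y2="172.000"/>
<text x="336.113" y="169.000" text-anchor="middle">30</text>
<line class="tick" x1="391.484" y1="178.000" x2="391.484" y2="172.000"/>
<text x="391.484" y="169.000" text-anchor="middle">40</text>
<line class="tick" x1="446.855" y1="178.000" x2="446.855" y2="172.000"/>
<text x="446.855" y="169.000" text-anchor="middle">50</text>
<line class="tick" x1="502.227" y1="178.000" x2="502.227" y2="172.000"/>
<text x="502.227" y="169.000" text-anchor="middle">60</text>
<line class="tick" x1="557.598" y1="178.000" x2="557.598" y2="172.000"/>
<text x="557.598" y="169.000" text-anchor="middle">70</text>
<line class="tick" x1="612.969" y1="178.000" x2="612.969" y2="172.000"/>
<text x="612.969" y="169.000" text-anchor="middle">80</text>
<line class="tick" x1="668.340" y1="178.000" x2="668.340" y2="172.000"/>
<text x="668.340" y="169.000" text-anchor="middle">90</text>
<line class="tick" x1="723.711" y1="178.000" x2="723.711" y2="172.000"/>
<text x="723.711" y="169.000" text-anchor="middle">100</text>
<line class="tick" x1="779.082" y1="178.000" x2="779.082" y2="172.000"/>
<text x="779.082" y="169.000" text-anchor="middle">110</text>
<text class="lab" x="10.000" y="228.000">Predicted value</text>
<line class="ruler" x1="170.000" y1="224.000" x2="800.000" y2="224.000"/>
<line class="tick" x1="192.969" y1="224.000" x2="192.969" y2="218.000"/>
<text x="192.969" y="215.000" text-anchor="middle">2</text>
<line class="tick" x1="258.594" y1="224.000" x2="258.594" y2="218.000"/>
<text x="258.594" y="215.000" text-anchor="middle">4</text>
<line class="tick" x1="324.219" y1="224.000" x2="324.219" y2="218.000"/>
<text x="324.219" y="215.000" text-anchor="middle">6</text>
<line class="tick" x1="389.844" y1="224.000" x2="389.844" y2="218.000"/>
<text x="389.844" y="215.000" text-anchor="middle">8</text>
<line class="tick" x1="455.469" y1="224.000" x2="455.469" y2="218.000"/>
<text x="455.469" y="215.000" text-anchor="middle">10</text>
<line class="tick" x1="521.094" y1="224.000" x2="521.094" y2="218.000"/>
<text x="521.094" y="215.000" text-anchor="middle">12</text>
<line class="tick" x1="586.719" y1="224.000" x2="586.719" y2="218.000"/>
<text x="586.719" y="215.000" text-anchor="middle">14</text>
<line class="tick" x1="652.344" y1="224.000" x2="652.344" y2="218.000"/>
<text x="652.344" y="215.000" text-anchor="middle">16</text>
<line class="tick" x1="717.969" y1="224.000" x2="717.969" y2="218.000"/>
<text x="717.969" y="215.000" text-anchor="middle">18</text>
<line class="tick" x1="783.594" y1="224.000" x2="783.594" y2="218.000"/>
<text x="783.594" y="215.000" text-anchor="middle">20</text>
</svg>
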