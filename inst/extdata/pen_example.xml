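<?xml version="1.0" encoding="UTF-8"?>
<annotation>
  <filename>pen_example.png</filename>
  <size>
    <width>320</width>
    <height>240</height>
    <depth>3</depth>
  </size>
  <object>
    <name>lying</name>
    <difficult>0</difficult>
    <bndbox>
      <xmin>99</xmin>
      <ymin>48</ymin>
      <xmax>162</xmax>
      <ymax>82</ymax>
    </bndbox>
  </object>
  <object>
    <name>lying</name>
    <difficult>0</difficult>
    <bndbox>
      <xmin>167</xmin>
      <ymin>70</ymin>
      <xmax>210</xmax>
      <ymax>126</ymax>
    </bndbox>
  </object>
  <object>
    <name>stand</name>
    <difficult>0</difficult>
    <bndbox>
      <xmin>156</xmin>
      <ymin>206</ymin>
      <xmax>207</xmax>
      <ymax>240</ymax>
    </bndbox>
  </object>
  <object>
    <name>lying</name>
    <difficult>0</difficult>
    <bndbox>
      <xmin>253</xmin>
      <ymin>180</ymin>
      <xmax>303</xmax>
      <ymax>240</ymax>
    </bndbox>
  </object>
</annotation>
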